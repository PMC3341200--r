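#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void pias3net_initmod(void (*odeparms)(int *, double *));
void pias3net_derivs(int *neq, double *t, double *y, double *ydot,
                     double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"pias3net_initmod", (DL_FUNC) &pias3net_initmod, 1},
    {"pias3net_derivs",  (DL_FUNC) &pias3net_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_pias3net(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
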