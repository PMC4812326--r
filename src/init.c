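#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void sls_initmod(void (*odeparms)(int *, double *));
void sls_derivs(int *neq, double *t, double *y, double *ydot,
                double *yout, int *ip);

static const R_CMethodDef CEntries[] = {
    {"sls_initmod", (DL_FUNC) &sls_initmod, 1},
    {"sls_derivs",  (DL_FUNC) &sls_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_fiberSLS(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
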