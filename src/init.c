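#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

void sscf_initmod(void (*odeparms)(int *, double *));
void sscf_derivs(int *, double *, double *, double *, double *, int *);

static const R_CMethodDef CEntries[] = {
    {"sscf_initmod", (DL_FUNC) &sscf_initmod, 1},
    {"sscf_derivs",  (DL_FUNC) &sscf_derivs,  6},
    {NULL, NULL, 0}
};

void R_init_sscfkin(DllInfo *dll)
{
    R_registerRoutines(dll, CEntries, NULL, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
    /* symbol lookup by name must stay possible for deSolve */
    R_forceSymbols(dll, FALSE);
}
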