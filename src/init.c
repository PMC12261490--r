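#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP marlene_set_blas_threads(SEXP);

static const R_CallMethodDef CallEntries[] = {
    {"marlene_set_blas_threads", (DL_FUNC) &marlene_set_blas_threads, 1},
    {NULL, NULL, 0}
};

void R_init_marlene(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
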