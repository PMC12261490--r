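/* The model's dense kernels are small (tens-by-tens matrices), where
 * multi-threaded BLAS spin-up costs more than the arithmetic. If the linked
 * BLAS is OpenBLAS, cap its thread count; otherwise do nothing. */
#include <R.h>
#include <Rinternals.h>

#ifdef _WIN32
SEXP marlene_set_blas_threads(SEXP n) { return ScalarLogical(0); }
#else
#include <dlfcn.h>

typedef void (*set_threads_t)(int);

SEXP marlene_set_blas_threads(SEXP n)
{
    set_threads_t f =
        (set_threads_t) dlsym(RTLD_DEFAULT, "openblas_set_num_threads");
    if (f == NULL)
        return ScalarLogical(0);
    f(asInteger(n));
    return ScalarLogical(1);
}
#endif
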