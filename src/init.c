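#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

SEXP C_des_ecb(SEXP data, SEXP key, SEXP decrypt_);

static const R_CallMethodDef CallEntries[] = {
    {"C_des_ecb", (DL_FUNC) &C_des_ecb, 3},
    {NULL, NULL, 0}
};

void R_init_beadio(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
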