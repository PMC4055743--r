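#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP ma_set_scheme(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
extern SEXP ma_set_rates(SEXP);
extern void ma_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef callMethods[] = {
    {"ma_set_scheme", (DL_FUNC) &ma_set_scheme, 6},
    {"ma_set_rates",  (DL_FUNC) &ma_set_rates,  1},
    {NULL, NULL, 0}
};

/* registered as a .C-style symbol so deSolve can resolve "ma_derivs" */
static const R_CMethodDef cMethods[] = {
    {"ma_derivs", (DL_FUNC) &ma_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_sfkin(DllInfo *info)
{
    R_registerRoutines(info, cMethods, callMethods, NULL, NULL);
    R_useDynamicSymbols(info, FALSE);
}
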