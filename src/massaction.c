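/* Mass-action right-hand side for deSolve, driven by a scheme loaded from R.
 *
 * The scheme (reactant indices, stoichiometry, rate values) is held in
 * static storage set by ma_set_scheme() immediately before each integration;
 * deSolve then calls ma_derivs() by symbol without any R-level overhead.
 * Reactions are elementary (at most bimolecular): r2[j] == 0 marks a
 * unimolecular reaction.
 */

#include <R.h>
#include <Rinternals.h>
#include <string.h>

static int n_sp = 0, n_rx = 0;
static int *r1 = NULL, *r2 = NULL;
static double *stoich = NULL; /* n_sp x n_rx, column-major */
static double *kv = NULL;

SEXP ma_set_scheme(SEXP sp, SEXP rx, SEXP R1, SEXP R2, SEXP N, SEXP K)
{
    n_sp = INTEGER(sp)[0];
    n_rx = INTEGER(rx)[0];
    if (r1) { R_Free(r1); R_Free(r2); R_Free(stoich); R_Free(kv); }
    r1 = R_Calloc(n_rx, int);
    r2 = R_Calloc(n_rx, int);
    stoich = R_Calloc((size_t) n_sp * n_rx, double);
    kv = R_Calloc(n_rx, double);
    memcpy(r1, INTEGER(R1), n_rx * sizeof(int));
    memcpy(r2, INTEGER(R2), n_rx * sizeof(int));
    memcpy(stoich, REAL(N), (size_t) n_sp * n_rx * sizeof(double));
    memcpy(kv, REAL(K), n_rx * sizeof(double));
    return R_NilValue;
}

SEXP ma_set_rates(SEXP K)
{
    if (!kv || LENGTH(K) != n_rx)
        error("scheme not loaded or rate vector length mismatch");
    memcpy(kv, REAL(K), n_rx * sizeof(double));
    return R_NilValue;
}

void ma_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    int i, j;
    for (i = 0; i < *neq; i++) ydot[i] = 0.0;
    for (j = 0; j < n_rx; j++) {
        double v = kv[j] * y[r1[j] - 1];
        const double *col = stoich + (size_t) j * n_sp;
        if (r2[j] > 0) v *= y[r2[j] - 1];
        for (i = 0; i < n_sp; i++)
            if (col[i] != 0.0) ydot[i] += col[i] * v;
    }
}
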