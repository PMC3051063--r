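/* Generic mass-action ODE right-hand side for deSolve.
 *
 * A model is packed on the R side into a single double vector:
 *   p[0] = nsp   (number of species)
 *   p[1] = nrx   (number of reactions)
 *   p[2] = mo    (maximum reaction order, >= 1)
 *   p[3 .. 3+nrx-1]                 = rate constants k
 *   p[3+nrx .. 3+nrx+nrx*mo-1]      = factor matrix F (nrx x mo,
 *                                     column-major; 1-based species index,
 *                                     0 = no factor)
 *   p[3+nrx+nrx*mo .. end]          = stoichiometry S (nsp x nrx,
 *                                     column-major)
 *
 * The packed model is installed with massaction_set() before integration;
 * deSolve then calls massaction_derivs() by symbol name.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP ma_model = NULL;

SEXP massaction_set(SEXP packed)
{
    if (TYPEOF(packed) != REALSXP)
        error("packed model must be a double vector");
    if (ma_model != NULL)
        R_ReleaseObject(ma_model);
    ma_model = packed;
    R_PreserveObject(ma_model);
    return R_NilValue;
}

static void ma_rhs(const double *p, const double *y, double *ydot)
{
    const int nsp = (int) p[0];
    const int nrx = (int) p[1];
    const int mo  = (int) p[2];
    const double *k = p + 3;
    const double *F = p + 3 + nrx;
    const double *S = p + 3 + nrx + (size_t) nrx * mo;
    int i, j, c;

    for (i = 0; i < nsp; i++)
        ydot[i] = 0.0;
    for (j = 0; j < nrx; j++) {
        double v = k[j];
        for (c = 0; c < mo; c++) {
            int idx = (int) F[j + (size_t) c * nrx];
            if (idx > 0)
                v *= y[idx - 1];
        }
        if (v != 0.0) {
            const double *Sj = S + (size_t) j * nsp;
            for (i = 0; i < nsp; i++)
                ydot[i] += Sj[i] * v;
        }
    }
}

void massaction_derivs(int *neq, double *t, double *y, double *ydot,
                       double *yout, int *ip)
{
    (void) neq; (void) t; (void) yout; (void) ip;
    if (ma_model == NULL)
        error("no mass-action model installed");
    ma_rhs(REAL(ma_model), y, ydot);
}

SEXP massaction_eval(SEXP packed, SEXP y)
{
    const double *p;
    SEXP ydot;
    if (TYPEOF(packed) != REALSXP || TYPEOF(y) != REALSXP)
        error("packed model and state must be double vectors");
    p = REAL(packed);
    if (XLENGTH(y) != (R_xlen_t) p[0])
        error("state length does not match the packed model");
    ydot = PROTECT(allocVector(REALSXP, XLENGTH(y)));
    ma_rhs(p, REAL(y), REAL(ydot));
    UNPROTECT(1);
    return ydot;
}

static const R_CallMethodDef call_entries[] = {
    {"massaction_set",  (DL_FUNC) &massaction_set,  1},
    {"massaction_eval", (DL_FUNC) &massaction_eval, 2},
    {NULL, NULL, 0}
};

void R_init_nfkbdrug(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* keep dynamic lookup enabled so deSolve can resolve
       "massaction_derivs" by name */
    R_useDynamicSymbols(dll, TRUE);
}
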