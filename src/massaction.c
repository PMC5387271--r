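/* Compiled mass-action right-hand side for deSolve.
 *
 * The model is flattened into a numeric descriptor vector installed via
 * kp_set_model() immediately before each integration (single-threaded R;
 * forked workers each hold their own copy):
 *
 *   [0]            ns   number of species
 *   [1]            nr   number of reactions
 *   [2 .. 2+nr)         rate constants k_j
 *   [.. + ns*nr)        stoichiometry matrix S (column-major, fixed rows 0)
 *   [.. + nr)           reactant multiset size per reaction
 *   [.. + sum sizes)    0-based reactant species indices, concatenated
 *
 * Propensity of reaction j: k_j times the product of the current reactant
 * amounts (one factor per multiset entry); dy = S a.
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

static SEXP kp_desc_sexp = NULL;
static double *kp_desc = NULL;

SEXP kp_set_model(SEXP desc)
{
    if (TYPEOF(desc) != REALSXP)
        error("model descriptor must be a double vector");
    if (kp_desc_sexp != NULL)
        R_ReleaseObject(kp_desc_sexp);
    kp_desc_sexp = desc;
    R_PreserveObject(kp_desc_sexp);
    kp_desc = REAL(desc);
    return R_NilValue;
}

void kp_derivs(int *neq, double *t, double *y, double *ydot,
               double *yout, int *ip)
{
    const double *d = kp_desc;
    const int ns = (int) d[0];
    const int nr = (int) d[1];
    const double *k = d + 2;
    const double *S = d + 2 + nr;
    const double *nre = d + 2 + nr + (size_t) ns * nr;
    const double *idx = nre + nr;
    int off = 0;

    for (int i = 0; i < ns; i++)
        ydot[i] = 0.0;
    for (int j = 0; j < nr; j++) {
        double a = k[j];
        const int m = (int) nre[j];
        for (int q = 0; q < m; q++)
            a *= y[(int) idx[off + q]];
        off += m;
        const double *Sc = S + (size_t) j * ns;
        for (int i = 0; i < ns; i++)
            ydot[i] += Sc[i] * a;
    }
}

static const R_CallMethodDef call_methods[] = {
    {"kp_set_model", (DL_FUNC) &kp_set_model, 1},
    {NULL, NULL, 0}
};

static const R_CMethodDef c_methods[] = {
    {"kp_derivs", (DL_FUNC) &kp_derivs, 6},
    {NULL, NULL, 0}
};

void R_init_kinpipe(DllInfo *dll)
{
    R_registerRoutines(dll, c_methods, call_methods, NULL, NULL);
    R_useDynamicSymbols(dll, TRUE);
}
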