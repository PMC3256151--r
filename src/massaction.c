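/* Generic mass-action right-hand side for the tissue factor pathway network.
 *
 * The reaction network is not hard-coded here: R flattens the reaction table
 * (rate constant, reactant indices, product indices per reaction arrow) into
 * a fixed-length parameter vector, so this file stays a single generic
 * mass-action engine and the network definition lives in one place on the R
 * side. Layout of the parameter vector:
 *
 *   parms[0] = n_species
 *   parms[1] = n_reactions
 *   then 9 doubles per reaction:
 *     k, n_reactants, r1, r2, n_products, p1, p2, p3, p4
 *   (species indices 0-based; unused slots -1; vector zero-padded to
 *    PARMS_LEN so the deSolve initializer has a fixed length)
 */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

#define MAX_REACTIONS 64
#define SLOTS_PER_REACTION 9
#define PARMS_LEN (2 + MAX_REACTIONS * SLOTS_PER_REACTION)

static double parms[PARMS_LEN];

/* deSolve parameter initializer */
void xagen_initmod(void (*odeparms)(int *, double *))
{
    int n = PARMS_LEN;
    odeparms(&n, parms);
}

static void mass_action_rhs(const double *p, const double *y, double *dydt)
{
    const int n_species = (int) p[0];
    const int n_reactions = (int) p[1];
    int i, j;

    for (i = 0; i < n_species; i++) dydt[i] = 0.0;

    for (j = 0; j < n_reactions; j++) {
        const double *r = p + 2 + j * SLOTS_PER_REACTION;
        double flux = r[0];
        int n_re = (int) r[1];
        int n_pr = (int) r[4];

        for (i = 0; i < n_re; i++) flux *= y[(int) r[2 + i]];
        for (i = 0; i < n_re; i++) dydt[(int) r[2 + i]] -= flux;
        for (i = 0; i < n_pr; i++) dydt[(int) r[5 + i]] += flux;
    }
}

/* deSolve derivative callback */
void xagen_derivs(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    mass_action_rhs(parms, y, ydot);
}

/* Classical fixed-step fourth-order Runge-Kutta integrator over the same
 * parameter encoding; used as the independent integration scheme against
 * which the adaptive solution is verified. Samples (including t = 0) are
 * returned every `sample_every` steps.
 */
SEXP C_rk4_integrate(SEXP s_y0, SEXP s_parms, SEXP s_dt, SEXP s_nsteps,
                     SEXP s_sample_every)
{
    const double *p = REAL(s_parms);
    const int n = (int) p[0];
    const double dt = REAL(s_dt)[0];
    const R_xlen_t nsteps = (R_xlen_t) REAL(s_nsteps)[0];
    const R_xlen_t sample_every = (R_xlen_t) REAL(s_sample_every)[0];

    if (XLENGTH(s_y0) < n) error("state vector shorter than n_species");
    if (XLENGTH(s_parms) < 2 + ((R_xlen_t) p[1]) * SLOTS_PER_REACTION)
        error("parameter vector truncated");

    R_xlen_t n_samples = nsteps / sample_every + 1;
    SEXP out = PROTECT(allocMatrix(REALSXP, (int) n_samples, n));
    double *o = REAL(out);

    double *y = (double *) R_alloc(n, sizeof(double));
    double *k1 = (double *) R_alloc(n, sizeof(double));
    double *k2 = (double *) R_alloc(n, sizeof(double));
    double *k3 = (double *) R_alloc(n, sizeof(double));
    double *k4 = (double *) R_alloc(n, sizeof(double));
    double *tmp = (double *) R_alloc(n, sizeof(double));
    int i;
    R_xlen_t step, row = 0;

    for (i = 0; i < n; i++) y[i] = REAL(s_y0)[i];
    for (i = 0; i < n; i++) o[row + n_samples * i] = y[i];
    row++;

    for (step = 1; step <= nsteps; step++) {
        mass_action_rhs(p, y, k1);
        for (i = 0; i < n; i++) tmp[i] = y[i] + 0.5 * dt * k1[i];
        mass_action_rhs(p, tmp, k2);
        for (i = 0; i < n; i++) tmp[i] = y[i] + 0.5 * dt * k2[i];
        mass_action_rhs(p, tmp, k3);
        for (i = 0; i < n; i++) tmp[i] = y[i] + dt * k3[i];
        mass_action_rhs(p, tmp, k4);
        for (i = 0; i < n; i++)
            y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

        if (step % sample_every == 0) {
            for (i = 0; i < n; i++) o[row + n_samples * i] = y[i];
            row++;
        }
        if (step % 1000000 == 0) R_CheckUserInterrupt();
    }

    UNPROTECT(1);
    return out;
}

/* Direct (non-deSolve) evaluation of the RHS, for tests */
SEXP C_mass_action_rhs(SEXP s_y, SEXP s_parms)
{
    const double *p = REAL(s_parms);
    const int n = (int) p[0];
    SEXP out = PROTECT(allocVector(REALSXP, n));
    mass_action_rhs(p, REAL(s_y), REAL(out));
    UNPROTECT(1);
    return out;
}

static const R_CallMethodDef call_entries[] = {
    {"C_rk4_integrate", (DL_FUNC) &C_rk4_integrate, 5},
    {"C_mass_action_rhs", (DL_FUNC) &C_mass_action_rhs, 2},
    {NULL, NULL, 0}
};

void R_init_xagen(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    /* deSolve resolves "xagen_derivs"/"xagen_initmod" by name */
    R_useDynamicSymbols(dll, TRUE);
}
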