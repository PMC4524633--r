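/* Compiled right-hand side for the windowed GMA simulations.
 *
 * The pool derivatives are S %*% v with v_j = a_j(t) * x_sub(j), where the
 * per-flux effective activity a_j(t) (coefficient * smoothed activity *
 * boundary drivers) is supplied as a matrix over a fine time grid and
 * interpolated linearly.  Parameters are passed as one packed double
 * vector, padded to a fixed length for the deSolve initializer:
 *
 *   p[0] n_pool, p[1] n_flux, p[2] nG (grid rows), p[3] t0, p[4] dt
 *   p[5 ..]                 substrate index per flux (0 = none)
 *   p[5 + m ..]             S, column-major (n_pool x n_flux)
 *   p[5 + m + n*m ..]       activity grid, column-major (nG x n_flux)
 */

#include <R.h>
#include <math.h>

#define CERADYN_NP 80000
static double p[CERADYN_NP];

void ceradyn_init(void (*odeparms)(int *, double *))
{
    int n = CERADYN_NP;
    odeparms(&n, p);
}

/* Augmented right-hand side: states plus forward sensitivities with
 * respect to the window coefficients.  Because every flux is linear in
 * its substrate, the sensitivities s_k = dx/dC_k obey the same linear
 * system with a forcing term:
 *
 *   dx/dt  = S (C[e(j)] g_j(t) xf_j)
 *   ds_k/dt = S (C[e(j)] g_j(t) s_k[sub_j]) + S (1[e(j)=k] g_j(t) xf_j)
 *
 * Packed layout (padded to CERADYN_NP):
 *   p[0] n_pool, p[1] n_flux, p[2] nG, p[3] t0, p[4] dt, p[5] K
 *   p[6 ..]                      substrate index per flux (0 = none)
 *   p[6 + m ..]                  coefficient index per flux (1..K)
 *   p[6 + 2m ..]                 S, column-major (n x m)
 *   p[6 + 2m + n*m ..]           activity grid G, column-major (nG x m)
 *   p[6 + 2m + n*m + nG*m ..]    coefficients C (K)
 * States: y = [x (n), s_1 (n), ..., s_K (n)].
 */
void ceradyn_sens(int *neq, double *t, double *y, double *ydot,
                  double *yout, int *ip)
{
    int n = (int) p[0], m = (int) p[1], nG = (int) p[2];
    double t0 = p[3], dtg = p[4];
    int K = (int) p[5];
    double *sub = p + 6;
    double *cls = p + 6 + m;
    double *S = p + 6 + 2 * m;
    double *G = S + (size_t) n * m;
    double *C = G + (size_t) nG * m;
    double u = (*t - t0) / dtg;
    int i = (int) floor(u);
    if (i < 0) i = 0;
    if (i > nG - 2) i = nG - 2;
    double w = u - i;

    for (int k = 0; k < n * (1 + K); k++) ydot[k] = 0.0;
    for (int j = 0; j < m; j++) {
        double g = (1.0 - w) * G[i + (size_t) nG * j] +
                   w * G[i + 1 + (size_t) nG * j];
        if (g == 0.0) continue;
        int s = (int) sub[j];
        int e = (int) cls[j] - 1;
        double cg = C[e] * g;
        double xf = 1.0;
        int clipped = 0;
        if (s > 0) {
            xf = y[s - 1];
            if (xf < 0.0) { xf = 0.0; clipped = 1; }
        }
        double *Sj = S + (size_t) n * j;
        /* state part */
        double v = cg * xf;
        for (int k = 0; k < n; k++)
            if (Sj[k] != 0.0) ydot[k] += Sj[k] * v;
        /* sensitivity blocks; in clipped regions the flux neither responds
         * to the substrate nor to its coefficient */
        for (int q = 0; q < K; q++) {
            double *sq = y + n * (1 + q);
            double *dq = ydot + n * (1 + q);
            double vs = (s > 0 && !clipped) ? cg * sq[s - 1] : 0.0;
            if (q == e && !clipped) vs += g * xf;
            if (vs != 0.0)
                for (int k = 0; k < n; k++)
                    if (Sj[k] != 0.0) dq[k] += Sj[k] * vs;
        }
    }
}

void ceradyn_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int n = (int) p[0], m = (int) p[1], nG = (int) p[2];
    double t0 = p[3], dtg = p[4];
    double *sub = p + 5;
    double *S = p + 5 + m;
    double *G = p + 5 + m + (size_t) n * m;
    double u = (*t - t0) / dtg;
    int i = (int) floor(u);
    if (i < 0) i = 0;
    if (i > nG - 2) i = nG - 2;
    double w = u - i;

    for (int k = 0; k < n; k++) ydot[k] = 0.0;
    for (int j = 0; j < m; j++) {
        double g = (1.0 - w) * G[i + (size_t) nG * j] +
                   w * G[i + 1 + (size_t) nG * j];
        int s = (int) sub[j];
        double xf = 1.0;
        if (s > 0) {
            xf = y[s - 1];
            if (xf < 0.0) xf = 0.0;
        }
        double v = g * xf;
        if (v != 0.0) {
            double *Sj = S + (size_t) n * j;
            for (int k = 0; k < n; k++)
                if (Sj[k] != 0.0) ydot[k] += Sj[k] * v;
        }
    }
}
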