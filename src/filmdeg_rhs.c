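/* Method-of-lines right-hand side for the two-state enzymatic
 * degradation model, in the form expected by deSolve's compiled-model
 * interface (initfunc + derivs).
 *
 * State layout (length 6N): E | C | A | EC | EA | P, each a block of N
 * nodes on the uniform half-thickness grid.  Node 0 is the exposed
 * surface (Dirichlet E = 1, dE/dt = 0); node N-1 is the symmetry plane
 * (zero flux, half-control-volume correction).  Only free enzyme
 * diffuses; polymer phases, complexes and product are immobile.
 */
#include <R.h>

static double parms[11];
#define K1     parms[0]
#define KM1    parms[1]
#define K3     parms[2]
#define KM3    parms[3]
#define KCONV  parms[4]
#define KDEGC  parms[5]
#define KDEGA  parms[6]
#define DE0    parms[7]
#define ALPHAE parms[8]
#define NNODE  parms[9]
#define DX     parms[10]

void filmdeg_initmod(void (*odeparms)(int *, double *))
{
    int n = 11;
    odeparms(&n, parms);
}

void filmdeg_derivs(int *neq, double *t, double *y, double *ydot,
                    double *yout, int *ip)
{
    int N = (int) (NNODE + 0.5);
    const double *E = y, *C = y + N, *A = y + 2 * N,
                 *EC = y + 3 * N, *EA = y + 4 * N;
    double *dE = ydot, *dC = ydot + N, *dA = ydot + 2 * N,
           *dEC = ydot + 3 * N, *dEA = ydot + 4 * N, *dP = ydot + 5 * N;
    double dx2 = DX * DX;
    int i;

    /* reaction terms (mass action) */
    for (i = 0; i < N; i++) {
        double bC  = K1 * E[i] * C[i];   /* enzyme-crystalline binding   */
        double bA  = K3 * E[i] * A[i];   /* enzyme-amorphous binding     */
        double rC  = KM1 * EC[i];        /* crystalline dissociation     */
        double rA  = KM3 * EA[i];        /* amorphous dissociation       */
        double cv  = KCONV * EC[i];      /* amorphisation                */
        double gC  = KDEGC * EC[i];      /* crystalline enzymolysis      */
        double gA  = KDEGA * EA[i];      /* amorphous enzymolysis        */

        dE[i]  = -bC + rC - bA + rA + cv + gC + gA;
        dC[i]  = -bC + rC;
        dA[i]  = -bA + rA + cv;
        dEC[i] = bC - rC - cv - gC;
        dEA[i] = bA - rA - gA;
        dP[i]  = gC + gA;
    }

    /* porosity-dependent diffusion of free enzyme, arithmetic-mean
     * interface diffusivities; porosity clipped to [0, 1] */
    {
        double De_prev, De_cur;
        double phi0 = 1.0 - (C[0] + A[0]);
        if (phi0 < 0.0) phi0 = 0.0;
        if (phi0 > 1.0) phi0 = 1.0;
        De_prev = DE0 * (1.0 + ALPHAE * phi0);

        for (i = 1; i < N; i++) {
            double phi = 1.0 - (C[i] + A[i]);
            double Dm;
            if (phi < 0.0) phi = 0.0;
            if (phi > 1.0) phi = 1.0;
            De_cur = DE0 * (1.0 + ALPHAE * phi);
            Dm = 0.5 * (De_prev + De_cur); /* D_{i-1/2} */
            if (i < N - 1) {
                double phi_n = 1.0 - (C[i + 1] + A[i + 1]);
                double De_next, Dp;
                if (phi_n < 0.0) phi_n = 0.0;
                if (phi_n > 1.0) phi_n = 1.0;
                De_next = DE0 * (1.0 + ALPHAE * phi_n);
                Dp = 0.5 * (De_cur + De_next); /* D_{i+1/2} */
                dE[i] += (Dp * (E[i + 1] - E[i]) - Dm * (E[i] - E[i - 1])) / dx2;
            } else {
                /* zero flux at x = L: half control volume */
                dE[i] += 2.0 * Dm * (E[i - 1] - E[i]) / dx2;
            }
            De_prev = De_cur;
        }
    }

    /* Dirichlet surface node held at the bath concentration */
    dE[0] = 0.0;
}
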