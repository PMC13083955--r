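#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pairwise forces for the coarse-grained chain:
//  - harmonic bonds between consecutive beads,
//  - harmonic elastic-network restraints,
//  - hydropathy-scaled 12-6 (Ashbaugh-Hatch) short-range term,
//  - Debye-Hueckel screened electrostatics.
// Bonded and restrained pairs are excluded from the non-bonded loop.
// Units: nm, ps, kJ/mol, Da, e.  1 kJ/mol = 1 Da nm^2 ps^-2.

struct ForceParams {
    int n;
    const double *m, *q, *lam, *sig;
    const int *bi, *bj; int nb; double bondR0, bondK;
    const int *ri, *rj; const double *rr0; int nr; double restraintK;
    double eps, ahCut2, dhCut2, kappa, bCoul;
    std::vector<char> excl; // n*n exclusion lookup
};

// nbCap > 0 clips the magnitude of each non-bonded pair force (soft-core
// warmup); bonds and restraints are never capped so strained chain
// geometry can relax while overlaps push apart gently.

static void computeForces(const std::vector<double> &x, std::vector<double> &f,
                          const ForceParams &p, double nbCap = 0.0) {
    std::fill(f.begin(), f.end(), 0.0);
    const int n = p.n;
    // bonds
    for (int k = 0; k < p.nb; ++k) {
        int i = p.bi[k], j = p.bj[k];
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < 1e-12) continue;
        double fr = -p.bondK * (r - p.bondR0) / r;
        f[3*i]   += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
        f[3*j]   -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
    }
    // elastic network
    for (int k = 0; k < p.nr; ++k) {
        int i = p.ri[k], j = p.rj[k];
        double dx = x[3*i] - x[3*j], dy = x[3*i+1] - x[3*j+1],
               dz = x[3*i+2] - x[3*j+2];
        double r = std::sqrt(dx*dx + dy*dy + dz*dz);
        if (r < 1e-12) continue;
        double fr = -p.restraintK * (r - p.rr0[k]) / r;
        f[3*i]   += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
        f[3*j]   -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
    }
    // non-bonded
    const double maxCut2 = std::max(p.ahCut2, p.dhCut2);
    for (int i = 0; i < n - 1; ++i) {
        const double xi = x[3*i], yi = x[3*i+1], zi = x[3*i+2];
        const double qi = p.q[i], li = p.lam[i], si = p.sig[i];
        for (int j = i + 1; j < n; ++j) {
            if (p.excl[(size_t)i * n + j]) continue;
            double dx = xi - x[3*j], dy = yi - x[3*j+1], dz = zi - x[3*j+2];
            double r2 = dx*dx + dy*dy + dz*dz;
            if (r2 >= maxCut2) continue;
            double r = std::sqrt(r2);
            if (r < 1e-9) r = 1e-9;
            double dudr = 0.0;
            if (r2 < p.ahCut2) {
                double sij = 0.5 * (si + p.sig[j]);
                double lij = 0.5 * (li + p.lam[j]);
                double s2 = sij*sij / r2;
                double sr6 = s2*s2*s2;
                double dlj = -24.0 * p.eps * (2.0*sr6*sr6 - sr6) / r;
                // r <= 2^(1/6) sigma  <=>  sr6 >= 1/2
                dudr += (sr6 >= 0.5) ? dlj : lij * dlj;
            }
            double qq = qi * p.q[j];
            if (qq != 0.0 && r2 < p.dhCut2) {
                dudr += -p.bCoul * qq * std::exp(-p.kappa*r) *
                        (p.kappa*r + 1.0) / r2;
            }
            if (dudr != 0.0) {
                if (nbCap > 0.0) {
                    if (dudr > nbCap) dudr = nbCap;
                    else if (dudr < -nbCap) dudr = -nbCap;
                }
                double fr = -dudr / r;
                f[3*i]   += fr*dx; f[3*i+1] += fr*dy; f[3*i+2] += fr*dz;
                f[3*j]   -= fr*dx; f[3*j+1] -= fr*dy; f[3*j+2] -= fr*dz;
            }
        }
    }
}

// BAOAB Langevin integrator.  Saves coordinates (and optionally
// velocities) every saveEvery steps; the first warmupSteps are run with
// force capping and are not saved (they precede t = 0).
// [[Rcpp::export(name = ".cgLangevin")]]
List cgLangevin(NumericMatrix coords0,
                NumericVector masses, NumericVector charges,
                NumericVector lambdas, NumericVector sigmas,
                IntegerMatrix bonds, double bondR0, double bondK,
                IntegerMatrix restraints, NumericVector restraintR0,
                double restraintK,
                double epsilon, double ahCutoff, double dhCutoff,
                double kappa, double bCoul,
                double kT, double friction, double dt,
                int nSteps, int saveEvery,
                int warmupSteps, double forceCap,
                bool saveVelocities) {
    const int n = coords0.nrow();
    if (saveEvery < 1) stop("saveEvery must be >= 1");
    ForceParams p;
    p.n = n;
    p.m = masses.begin(); p.q = charges.begin();
    p.lam = lambdas.begin(); p.sig = sigmas.begin();
    p.nb = bonds.nrow();
    std::vector<int> bi(p.nb), bj(p.nb);
    for (int k = 0; k < p.nb; ++k) { bi[k] = bonds(k,0)-1; bj[k] = bonds(k,1)-1; }
    p.bi = bi.data(); p.bj = bj.data();
    p.bondR0 = bondR0; p.bondK = bondK;
    p.nr = restraints.nrow();
    std::vector<int> ri(p.nr), rj(p.nr);
    for (int k = 0; k < p.nr; ++k) { ri[k] = restraints(k,0)-1; rj[k] = restraints(k,1)-1; }
    p.ri = ri.data(); p.rj = rj.data();
    p.rr0 = restraintR0.begin(); p.restraintK = restraintK;
    p.eps = epsilon; p.ahCut2 = ahCutoff*ahCutoff; p.dhCut2 = dhCutoff*dhCutoff;
    p.kappa = kappa; p.bCoul = bCoul;
    p.excl.assign((size_t)n * n, 0);
    for (int k = 0; k < p.nb; ++k) {
        p.excl[(size_t)bi[k]*n + bj[k]] = 1;
        p.excl[(size_t)bj[k]*n + bi[k]] = 1;
    }
    for (int k = 0; k < p.nr; ++k) {
        p.excl[(size_t)ri[k]*n + rj[k]] = 1;
        p.excl[(size_t)rj[k]*n + ri[k]] = 1;
    }

    std::vector<double> x(3*n), v(3*n), f(3*n);
    for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) x[3*i+d] = coords0(i, d);

    RNGScope rngScope;
    // Maxwell-Boltzmann initial velocities at the target temperature
    for (int i = 0; i < n; ++i) {
        double s = std::sqrt(kT / masses[i]);
        for (int d = 0; d < 3; ++d) v[3*i+d] = s * R::norm_rand();
    }

    const double aO = std::exp(-friction * dt);
    const double bO = std::sqrt(1.0 - aO*aO);
    // warmup thermostat: strong friction so energy released while the
    // soft core anneals is dissipated before production
    const double warmFriction = std::max(friction, 5.0);
    const double aW = std::exp(-warmFriction * dt);
    const double bW = std::sqrt(1.0 - aW*aW);
    const double capMax = 1e6;

    const int nSave = nSteps / saveEvery;
    NumericVector outCoords((size_t)n * 3 * std::max(nSave, 1));
    NumericVector outVel(saveVelocities ? (size_t)n * 3 * std::max(nSave, 1) : 1);
    NumericVector outTimes(std::max(nSave, 1));

    computeForces(x, f, p, warmupSteps > 0 ? forceCap : 0.0);
    // soft-core warmup (not counted in trajectory time): the cap on
    // non-bonded pair forces is annealed upward so overlaps are squeezed
    // out gradually instead of detonating when the full core returns
    for (int step = 0; step < warmupSteps; ++step) {
        for (int i = 0; i < n; ++i) {
            double hdt = 0.5 * dt / p.m[i];
            for (int d = 0; d < 3; ++d) v[3*i+d] += hdt * f[3*i+d];
        }
        for (int k = 0; k < 3*n; ++k) x[k] += 0.5 * dt * v[k];
        for (int i = 0; i < n; ++i) {
            double s = std::sqrt(kT / p.m[i]);
            for (int d = 0; d < 3; ++d)
                v[3*i+d] = aW * v[3*i+d] + bW * s * R::norm_rand();
        }
        for (int k = 0; k < 3*n; ++k) x[k] += 0.5 * dt * v[k];
        double frac = warmupSteps > 1 ? (double)(step + 1) / warmupSteps : 1.0;
        double capNow = (step + 1 < warmupSteps)
            ? forceCap * std::pow(capMax / forceCap, frac)
            : 0.0;
        computeForces(x, f, p, capNow);
        for (int i = 0; i < n; ++i) {
            double hdt = 0.5 * dt / p.m[i];
            for (int d = 0; d < 3; ++d) v[3*i+d] += hdt * f[3*i+d];
        }
    }

    int saved = 0;
    for (int step = 1; step <= nSteps; ++step) {
        for (int i = 0; i < n; ++i) {
            double hdt = 0.5 * dt / p.m[i];
            for (int d = 0; d < 3; ++d) v[3*i+d] += hdt * f[3*i+d];
        }
        for (int k = 0; k < 3*n; ++k) x[k] += 0.5 * dt * v[k];
        for (int i = 0; i < n; ++i) {
            double s = std::sqrt(kT / p.m[i]);
            for (int d = 0; d < 3; ++d)
                v[3*i+d] = aO * v[3*i+d] + bO * s * R::norm_rand();
        }
        for (int k = 0; k < 3*n; ++k) x[k] += 0.5 * dt * v[k];
        computeForces(x, f, p);
        for (int i = 0; i < n; ++i) {
            double hdt = 0.5 * dt / p.m[i];
            for (int d = 0; d < 3; ++d) v[3*i+d] += hdt * f[3*i+d];
        }
        if (step % saveEvery == 0) {
            for (int k = 0; k < 3*n; ++k) {
                if (!std::isfinite(x[k]))
                    stop("non-finite coordinate at frame %d (step %d)",
                         saved + 1, step);
            }
            size_t off = (size_t)saved * 3 * n;
            for (int i = 0; i < n; ++i)
                for (int d = 0; d < 3; ++d)
                    outCoords[off + (size_t)d*n + i] = x[3*i+d];
            if (saveVelocities)
                for (int i = 0; i < n; ++i)
                    for (int d = 0; d < 3; ++d)
                        outVel[off + (size_t)d*n + i] = v[3*i+d];
            outTimes[saved] = step * dt;
            ++saved;
        }
        if (step % 2000 == 0) checkUserInterrupt();
    }

    NumericMatrix finalCoords(n, 3), finalVel(n, 3);
    for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
            finalCoords(i, d) = x[3*i+d];
            finalVel(i, d) = v[3*i+d];
        }

    return List::create(_["coords"] = outCoords, _["times"] = outTimes,
                        _["nSaved"] = saved,
                        _["velocities"] = saveVelocities ? (SEXP)outVel
                                                         : R_NilValue,
                        _["finalCoords"] = finalCoords,
                        _["finalVelocities"] = finalVel);
}
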