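#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Forward-Euler integration of the membrane/synapse network.
//
// State per neuron: voltage V (mV) and graded synaptic activity s in [0,1].
//   C dV/dt = -Gc (V - Ecell) - (Igap + Isyn) / scale + Iext
//   ds/dt   = ar * phi(V) * (1 - s) - ad * s,  phi = 1/(1+exp(-beta (V - Vth)))
// with Igap_i = sum_j Gg_ij (V_i - V_j), Isyn_i = sum_j Gs_ij s_j (V_i - Erev_j).
// scale_i = 1 + mu * m_i is the swelling factor dividing the coupling currents;
// scale_i = 1 recovers the healthy equation bit-for-bit (x / 1.0 == x in IEEE).
//
// Units: mV, pS, pF, s; currents in pS*mV (arbitrary units).
// [[Rcpp::export]]
Rcpp::List sim_euler_cpp(arma::vec V, arma::vec s,
                         const arma::mat& Gg, const arma::mat& Gs,
                         const arma::vec& Erev, const arma::vec& Vth,
                         double C, double Gc, double Ecell,
                         double beta, double ar, double ad,
                         const arma::vec& scale, const arma::vec& Iext,
                         double dt, int nsteps, int stride,
                         const arma::uvec& rec_idx, double vbound,
                         double t0)
{
    const uword n = V.n_elem;
    const vec gg_row = sum(Gg, 1);          // row sums, constant in time

    const int nrec = nsteps / stride + 1;   // includes the initial state
    mat Vrec(nrec, rec_idx.n_elem);
    vec times(nrec);

    int r = 0;
    times(r) = t0;
    Vrec.row(r) = V.elem(rec_idx).t();
    ++r;

    for (int k = 1; k <= nsteps; ++k) {
        const vec gs_s = Gs * s;
        const vec igap = V % gg_row - Gg * V;
        const vec isyn = V % gs_s - Gs * (s % Erev);
        const vec vdot = (-Gc * (V - Ecell) - (igap + isyn) / scale + Iext) / C;

        // overflow-guarded sigmoid
        vec x = -beta * (V - Vth);
        x.transform([](double u) { return u > 50.0 ? 50.0 : (u < -50.0 ? -50.0 : u); });
        const vec phi = 1.0 / (1.0 + exp(x));
        const vec sdot = ar * (phi % (1.0 - s)) - ad * s;

        V += dt * vdot;
        s += dt * sdot;
        s = clamp(s, 0.0, 1.0);

        if (!V.is_finite() || abs(V).max() > vbound) {
            uword bad = 0;
            for (uword i = 0; i < n; ++i) {
                if (!std::isfinite(V(i)) || std::abs(V(i)) > vbound) { bad = i; break; }
            }
            Rcpp::stop("simulation diverged at t = %g s (neuron index %d)",
                       t0 + k * dt, (int)(bad + 1));
        }

        if (k % stride == 0) {
            times(r) = t0 + k * dt;
            Vrec.row(r) = V.elem(rec_idx).t();
            ++r;
        }
    }

    return Rcpp::List::create(
        Rcpp::Named("times") = times,
        Rcpp::Named("V_samples") = Vrec,
        Rcpp::Named("V_final") = V,
        Rcpp::Named("s_final") = s,
        Rcpp::Named("t_final") = t0 + nsteps * dt);
}
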