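#include <Rcpp.h>
using namespace Rcpp;

// Coordinate-descent engine for the fast Laplace model and its weighted /
// Gaussian-prior variants. One call runs up to `max_sweeps` full sweeps of
//   (optional intercept update) -> per-marker update -> variance updates
// on the current state and returns the updated state. The caller owns all
// bookkeeping invariants: `resid` must equal y - mu - M beta on entry.
//
// prior codes: 0 = laplace (per-marker tau_j^-2 = lambda2 sigma2_e / sigma2_bj),
//              1 = gaussian (single pooled regularizer, updated once per sweep),
//              2 = fixed (tau_inv2 never touched; test/oracle mode).
//
// col_sq_w[j] holds m_j' Omega m_j; entries <= 0 mark markers excluded from
// the sweep (monomorphic columns), whose beta stays at its entry value.

// [[Rcpp::export]]
List flm_engine_cpp(const NumericVector y, const NumericMatrix M,
                    const NumericVector w,
                    double mu, NumericVector beta_in,
                    NumericVector tau_inv2_in,
                    double resid_var, NumericVector resid_in,
                    const double lambda2, const NumericVector col_sq_w,
                    const int prior,
                    const bool use_intercept,
                    const bool update_variances,
                    const int max_sweeps, const double tol,
                    const double var_floor, const double tau_cap)
{
    const int n = y.size(), p = M.ncol();
    NumericVector beta = clone(beta_in);
    NumericVector tau_inv2 = clone(tau_inv2_in);
    NumericVector resid = clone(resid_in);
    NumericVector beta_var(p, NA_REAL);

    double sw = 0.0;
    for (int i = 0; i < n; ++i) sw += w[i];

    double lambda_r = tau_inv2[0];   // gaussian shared regularizer
    bool converged = false;
    double delta = NA_REAL;
    int sweeps_done = 0;

    for (int it = 1; it <= max_sweeps; ++it) {
        double d2 = 0.0;

        if (use_intercept) {
            double se = 0.0;
            for (int i = 0; i < n; ++i) se += w[i] * resid[i];
            const double dmu = se / sw;
            mu += dmu;
            for (int i = 0; i < n; ++i) resid[i] -= dmu;
        }

        for (int j = 0; j < p; ++j) {
            const double mm = col_sq_w[j];
            if (mm <= 0.0) continue;
            const double denom = mm + tau_inv2[j];
            double xe = 0.0;
            for (int i = 0; i < n; ++i) xe += w[i] * M(i, j) * resid[i];
            const double b_new = (xe + beta[j] * mm) / denom;
            const double db = b_new - beta[j];
            if (db != 0.0)
                for (int i = 0; i < n; ++i) resid[i] -= M(i, j) * db;
            beta[j] = b_new;
            d2 += db * db;

            double s2b = b_new * b_new + resid_var / denom;
            if (s2b < var_floor) s2b = var_floor;
            beta_var[j] = s2b;
            if (prior == 0 && update_variances) {
                // inverse-Gaussian conditional expectation (Laplace prior)
                double t_new = std::sqrt(lambda2 * resid_var / s2b);
                if (t_new > tau_cap) t_new = tau_cap;
                tau_inv2[j] = t_new;
            }
        }

        if (update_variances) {
            // weighted y'eps with an n-1 denominator: weights act as
            // relative precisions, so the count (not the weight sum) sets
            // the degrees of freedom
            double ye = 0.0;
            for (int i = 0; i < n; ++i) ye += w[i] * y[i] * resid[i];
            resid_var = ye / (n - 1.0);
            if (resid_var < var_floor) resid_var = var_floor;

            if (prior == 1) {
                double bb = 0.0, trace = 0.0;
                int p_poly = 0;
                for (int j = 0; j < p; ++j) {
                    if (col_sq_w[j] <= 0.0) continue;
                    bb += beta[j] * beta[j];
                    trace += 1.0 / (col_sq_w[j] + lambda_r);
                    ++p_poly;
                }
                if (p_poly > 0) {
                    double s2b = (bb + resid_var * trace) / p_poly;
                    if (s2b < var_floor) s2b = var_floor;
                    double lr = resid_var / s2b;
                    if (lr > tau_cap) lr = tau_cap;
                    lambda_r = lr;
                    for (int j = 0; j < p; ++j) tau_inv2[j] = lambda_r;
                }
            }
        }

        sweeps_done = it;
        delta = d2;
        if (d2 < tol) { converged = true; break; }
    }

    return List::create(
        _["mu"] = mu, _["beta"] = beta, _["beta_var"] = beta_var,
        _["tau_inv2"] = tau_inv2, _["resid_var"] = resid_var,
        _["resid"] = resid, _["n_iter"] = sweeps_done,
        _["converged"] = converged, _["delta"] = delta);
}
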