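#include <Rcpp.h>
using namespace Rcpp;

// One breeding season of T discrete steps.
//
// Phase logic: when not breeding, the individual forages (E += f_f) until
// the reserve covers the full cost of a successful attempt
// (E >= E_i + c*x*t_r); the step on which the threshold check passes is
// already the first breeding step. Each breeding step pays the care cost
// c*x, then draws a fresh hazard h (beta or constant, optionally inflated
// for clutch dependence) and a uniform u; the nest fails iff h > u, and a
// surviving step earns the breeding-time foraging income f_b.
// After t_r surviving steps the attempt succeeds
// and c fledglings are recorded. An attempt still open at step T is
// truncated with zero fledglings. All randomness comes from R's RNG so
// seasons are reproducible from .Random.seed.
//
// h_const = NA_REAL selects the beta hazard; otherwise every draw equals
// h_const (before the clutch-dependence multiplier).
// [[Rcpp::export]]
List season_core(int T, double E_i, int c, double f_f, double x, int t_r,
                 double alpha, double beta, double h_const,
                 double hazard_mult, double f_b, bool keep_trace) {
    const double threshold = E_i + (double)c * x * (double)t_r;
    const bool use_beta = ISNAN(h_const);

    double E = E_i;
    double acquired = 0.0, invested = 0.0;
    int fledglings = 0, n_attempts = 0, n_successes = 0;
    int steps_in_attempt = 0;   // 0 = currently foraging
    int attempt_start = 0;
    int last_success_end = 0;   // 0 = no success yet
    int last_complete_end = 0;  // end of last attempt that ran to completion

    std::vector<int> log_start, log_end;
    std::vector<int> log_outcome;  // 1 success, 0 failure, -1 truncated
    NumericVector energy_series(keep_trace ? T + 1 : 1);
    IntegerVector phase_series(keep_trace ? T : 1);
    if (keep_trace) energy_series[0] = E;

    for (int t = 1; t <= T; ++t) {
        bool breeding = steps_in_attempt > 0;
        if (!breeding) {
            if (E >= threshold) {   // decision and first breeding step share t
                breeding = true;
                ++n_attempts;
                attempt_start = t;
            }
        }
        if (breeding) {
            ++steps_in_attempt;
            // Care cost is sunk whatever happens this step (the analytic
            // lattice spacing 1 + c*x/f_f counts the failing step's cost);
            // foraging income f_b accrues only if the nest survives the
            // step's hazard test.
            E -= (double)c * x;
            invested += (double)c * x;
            double h = use_beta ? R::rbeta(alpha, beta) : h_const;
            h *= hazard_mult;
            if (h > 1.0) h = 1.0;
            double u = unif_rand();
            if (h > u) {            // nest destroyed this step
                log_start.push_back(attempt_start);
                log_end.push_back(t);
                log_outcome.push_back(0);
                last_complete_end = t;
                steps_in_attempt = 0;
            } else {
                E += f_b;
                acquired += f_b;
                if (steps_in_attempt == t_r) {
                    fledglings += c;
                    ++n_successes;
                    last_success_end = t;
                    last_complete_end = t;
                    log_start.push_back(attempt_start);
                    log_end.push_back(t);
                    log_outcome.push_back(1);
                    steps_in_attempt = 0;
                }
            }
        } else {
            E += f_f;
            acquired += f_f;
        }
        if (keep_trace) {
            energy_series[t] = E;
            phase_series[t - 1] = breeding ? 1 : 0;
        }
    }
    if (steps_in_attempt > 0) {     // season ended mid-attempt
        log_start.push_back(attempt_start);
        log_end.push_back(T);
        log_outcome.push_back(-1);
    }

    // Wasted time: everything after the last attempt that ran to
    // completion (success or failure); a final truncated attempt is pure
    // waste. All of T if nothing completed.
    int ex_time = (last_complete_end > 0) ? (T - last_complete_end) : T;
    int ex_time_succ = (last_success_end > 0) ? (T - last_success_end) : T;
    List out = List::create(
        _["fledglings"] = fledglings,
        _["n_attempts"] = n_attempts,
        _["n_successes"] = n_successes,
        _["acquired_energy"] = acquired,
        _["invested_energy"] = invested,
        _["excessive_reserve_time"] = ex_time,
        _["excessive_reserve_time_success"] = ex_time_succ,
        _["excessive_reserve_energy"] = E - E_i,
        _["final_energy"] = E);
    if (keep_trace) {
        out["energy_series"] = energy_series;
        out["phase_series"] = phase_series;
        out["attempt_start"] = wrap(log_start);
        out["attempt_end"] = wrap(log_end);
        out["attempt_outcome"] = wrap(log_outcome);
    }
    return out;
}
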