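# Independent oracles and small helpers shared across tests.

# Mass-action oracle for the binding isotherm: solve
#   K_a = theta / ((1 - theta) * (L/n - theta * P))
# for theta by bisection, independently of the closed-form expression.
theta_mass_action <- function(lipid_total, protein_total, n, K_a) {
  if (lipid_total == 0) return(0)
  f <- function(theta) {
    K_a * (1 - theta) * (lipid_total / n - theta * protein_total) - theta
  }
  upper <- min(1, lipid_total / (n * protein_total))
  uniroot(f, lower = 0, upper = upper, tol = 1e-15)$root
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# Durbin-Watson statistic of a residual trace
durbin_watson <- function(r) sum(diff(r)^2) / sum(r^2)
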