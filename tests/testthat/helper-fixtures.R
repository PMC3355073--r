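# Shared fixtures, built once per test run.

# published-style lymphocyte trend: birth 11.2 kb, slopes -1190/-126/-43 bp/yr
lym_params <- piecewise_params(11.2, c(-1.190, -0.126, -0.043))

# one seeded default healthy cohort reused by several files
default_cohort <- generate_cohort(default_healthy_config(seed = 101))

cohort_subset <- function(cohort, ss) cohort[cohort$subset == ss, ]

# independent OLS oracle: explicit normal-equations solve on the hinge basis
normal_equations_fit <- function(age, y, breakpoints = c(1, 18)) {
  X <- hinge_design(age, breakpoints)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}
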