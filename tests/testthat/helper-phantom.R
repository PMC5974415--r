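# Shared small fixtures, built once per test run.

small_phantom <- function(n = 32L, spacing = 0.25)
  phantom_spec(grid_shape = rep(n, 3), spacing = spacing,
               expression_spacing = 0.4)

# cached template / FA template / skeleton at the default study scale
.fixture_env <- new.env()

study_phantom <- function() {
  if (is.null(.fixture_env$ph)) .fixture_env$ph <- phantom_spec()
  .fixture_env$ph
}

study_fa_skeleton <- function() {
  if (is.null(.fixture_env$skel)) {
    fa <- skelex:::fa_template(study_phantom())
    .fixture_env$fa <- fa
    .fixture_env$skel <- skeletonize(fa)
  }
  list(fa = .fixture_env$fa, skel = .fixture_env$skel)
}

# fast same-modality registration settings for unit tests
fast_reg_cfg <- function(...)
  registration_config(metric = "ncc", rotation_search = 0, ...)

# independent rank-sum oracle: exhaustive enumeration of group
# assignments, U computed by direct pair counting (ties count 1/2)
ranksum_enum_oracle <- function(x, y,
                                alternative = c("two.sided", "greater",
                                                "less")) {
  alternative <- match.arg(alternative)
  pooled <- c(x, y)
  nx <- length(x); N <- length(pooled)
  u_of <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  U <- u_of(x, y)
  combos <- utils::combn(N, nx)
  Up <- apply(combos, 2, function(sel)
    u_of(pooled[sel], pooled[-sel]))
  mu <- nx * (N - nx) / 2
  eps <- 1e-9
  switch(alternative,
         two.sided = mean(abs(Up - mu) >= abs(U - mu) - eps),
         greater = mean(Up >= U - eps),
         less = mean(Up <= U + eps))
}

# the estimator's roundoff guard, applied when comparing permutation
# maxima against an observed score
perm_count_guard <- function(null_max, obs)
  mean(null_max >= obs - 1e-8 * (1 + abs(obs)))
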