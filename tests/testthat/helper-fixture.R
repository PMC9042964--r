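# Shared fixtures, built in code once per test run.

.fixture_env <- new.env()

ref_config <- function() {
  if (is.null(.fixture_env$cfg)) {
    .fixture_env$cfg <- make_reference_fixture()
  }
  .fixture_env$cfg
}

# reference deterministic accruals, cached
ref_accruals <- function() {
  if (is.null(.fixture_env$acc)) {
    cfg <- ref_config()
    .fixture_env$acc <- purrr::map(names(cfg$regimens),
                                   ~accrue_outcomes(cfg, .x))
  }
  .fixture_env$acc
}

# a config with no parameter uncertainty (degenerate distributions)
degenerate_config <- function() {
  cfg <- ref_config()
  cfg$uncertainty <- uncertainty_spec(rr_ci = NULL, default_spread = 0)
  cfg
}
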