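#' Neutral samples with recombination (msprime backend)
#'
#' Generates neutral coalescent samples with `rho > 0` by invoking the
#' bundled msprime driver through the system `python`, exchanging data in
#' ms-format text that is read back with [read_ms()]. Recombination leaves
#' expected HAF scores unchanged but shrinks their variance (independent
#' marginal genealogies along the window average out), so this backend is
#' generation-only plumbing: all scoring happens in R.
#'
#' Called automatically by [sim_neutral()] when `params$rho > 0`; the
#' backend seed is drawn from the R RNG, so results are reproducible under
#' `set.seed()`.
#'
#' @param params A [demography()] with `rho > 0` (`alpha >= 0` supported).
#' @param reps Number of replicates.
#' @return A list of [hap_matrix()] objects.
#' @export
sim_neutral_recomb <- function(params, reps) {
  stopifnot(inherits(params, "demography"), reps >= 1)
  script <- system.file("python", "msprime_neutral.py", package = "hafscore")
  if (script == "") {
    # during development (pkgload), fall back to the source tree
    script <- file.path("inst", "python", "msprime_neutral.py")
  }
  if (!file.exists(script)) {
    stop("msprime backend script not found", call. = FALSE)
  }
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") {
    stop("no python interpreter found for the recombination backend",
         call. = FALSE)
  }
  seed <- sample.int(.Machine$integer.max - 1L, 1L)
  tmp <- tempfile(fileext = ".ms")
  on.exit(unlink(tmp))
  status <- system2(py, c(script,
                          "--n", params$n, "--theta", params$theta,
                          "--rho", params$rho, "--alpha", params$alpha,
                          "--N", params$N, "--L", params$window_length,
                          "--reps", reps, "--seed", seed,
                          "--out", tmp))
  if (status != 0L) {
    stop("msprime backend exited with status ", status, call. = FALSE)
  }
  read_ms(tmp, window_length = params$window_length)
}
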