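#' Generate an oddball stimulus sequence
#'
#' Random standard/deviant ordering under the constraint that every deviant
#' is preceded by at least `min_separation` standards (also at the start of
#' the sequence, so two deviants can never be adjacent). Stimulus-onset
#' asynchronies are jittered uniformly around the nominal value.
#'
#' The arrangement is drawn uniformly over the compositions of the spare
#' standards (those beyond the mandatory `min_separation` run before each
#' deviant) into the `n_deviant + 1` inter-deviant slots.
#'
#' @param n_standard,n_deviant trial counts (e.g. 600 standards, 150
#'   deviants for an 80/20 oddball block).
#' @param min_separation minimum number of standards immediately before each
#'   deviant (default 2).
#' @param soa_nominal nominal stimulus-onset asynchrony in ms (default 800).
#' @param soa_jitter half-width of the uniform SOA jitter in ms (default 50).
#' @param seed integer seed; the sequence is deterministic given it.
#' @return object of class `oddball_sequence`: list with `trial_labels`
#'   (character vector over `"standard"`/`"deviant"`), `soa_ms`, and the
#'   generating parameters.
#' @export
generate_oddball_sequence <- function(n_standard, n_deviant,
                                      min_separation = 2,
                                      soa_nominal = 800, soa_jitter = 50,
                                      seed = 1L) {
  n_standard <- as.integer(n_standard); n_deviant <- as.integer(n_deviant)
  if (n_standard < min_separation * n_deviant)
    stop("infeasible separation constraint: need n_standard >= ",
         "min_separation * n_deviant (", min_separation, " * ", n_deviant,
         " = ", min_separation * n_deviant, " > ", n_standard, ")",
         call. = FALSE)
  set.seed(seed)
  n <- n_standard + n_deviant
  labels <- rep("standard", n)
  if (n_deviant > 0) {
    extra <- n_standard - min_separation * n_deviant
    # uniform composition of `extra` into n_deviant + 1 slots (stars & bars)
    if (extra > 0 && n_deviant >= 1) {
      cuts <- sort(sample.int(extra + n_deviant, n_deviant))
      gaps_extra <- diff(c(0L, cuts, extra + n_deviant + 1L)) - 1L
    } else {
      gaps_extra <- rep(0L, n_deviant + 1L)
    }
    gaps <- gaps_extra
    gaps[seq_len(n_deviant)] <- gaps[seq_len(n_deviant)] + min_separation
    pos <- cumsum(gaps[seq_len(n_deviant)] + 1L) # deviant positions
    labels[pos] <- "deviant"
  }
  soa <- soa_nominal + runif(n, -soa_jitter, soa_jitter)
  structure(list(trial_labels = labels, soa_ms = soa,
                 n_standard = n_standard, n_deviant = n_deviant,
                 min_separation = as.integer(min_separation),
                 soa_nominal = soa_nominal, soa_jitter = soa_jitter,
                 seed = as.integer(seed)),
            class = "oddball_sequence")
}
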