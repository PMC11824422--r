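#' Piecewise-constant demographic model
#'
#' Epoch sizes are relative to the ancestral effective size `N_Anc`: a
#' one-epoch (equilibrium) model is `epochs = 1`; a two-epoch model is
#' `epochs = c(1, nu)`; a three-epoch model is `epochs = c(1, nu1, nu2)`
#' with the most recent epoch last.  `change_times` gives the time of each
#' instantaneous size change before the present, in units of `2 * N_Anc`
#' generations, one per change, oldest first (so the values are strictly
#' decreasing toward the present).  Internally the model works with
#' inter-change epoch durations, which is also how the fit is
#' parameterized.
#'
#' @param epochs numeric vector of relative sizes, first entry must be 1.
#' @param change_times numeric vector, `length(epochs) - 1` times of size
#'   changes before present (decreasing), units of `2 * N_Anc` generations.
#' @param theta_s optional fitted synonymous population-scaled mutation rate
#'   (total over the monitored synonymous sites).
#' @param n optional sample size the model was fitted at.
#' @return an object of class `demographic_model`.
#' @export
#' @examples
#' demographic_model(c(1, 0.1), 0.05)          # two-epoch contraction
#' demographic_model(c(1, 5, 0.5), c(0.1, 0.02)) # three-epoch
demographic_model <- function(epochs, change_times = numeric(0),
                              theta_s = NA_real_, n = NA_integer_) {
  epochs <- as.numeric(epochs)
  change_times <- as.numeric(change_times)
  if (length(epochs) < 1 || epochs[1] != 1) {
    stop("epochs must start with the ancestral relative size 1")
  }
  if (any(epochs <= 0)) stop("all epoch sizes must be > 0")
  if (length(change_times) != length(epochs) - 1) {
    stop("need one change time per size change")
  }
  if (any(change_times <= 0)) stop("all change times must be > 0")
  if (length(change_times) > 1 && any(diff(change_times) >= 0)) {
    stop("change times must be strictly decreasing toward the present")
  }
  structure(list(epochs = epochs, change_times = change_times,
                 theta_s = theta_s, n = n),
            class = "demographic_model")
}

#' @export
print.demographic_model <- function(x, ...) {
  k <- length(x$epochs)
  cat(sprintf("%d-epoch demographic model\n", k))
  cat("  relative sizes (past -> present):",
      paste(signif(x$epochs, 4), collapse = ", "), "\n")
  if (k > 1) {
    cat("  change times (2*N_Anc gens before present):",
        paste(signif(x$change_times, 4), collapse = ", "), "\n")
  }
  if (!is.na(x$theta_s)) cat(sprintf("  theta_s = %g\n", x$theta_s))
  invisible(x)
}

# Durations of the non-ancestral epochs, oldest first.  For change times
# t1 > t2 > ... the epoch that started at t_i lasts t_i - t_{i+1} (the most
# recent one lasts t_last).
demog_durations <- function(model) {
  ct <- model$change_times
  if (length(ct) == 0) return(numeric(0))
  -diff(c(ct, 0))
}

n_free_params <- function(model) 2L * (length(model$epochs) - 1L)
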