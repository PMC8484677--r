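#' Kernel specifications for dynamic correlation estimation
#'
#' A kernel assigns each observation a weight describing how much it
#' contributes to the instantaneous correlation estimate at a given
#' timepoint \eqn{t}. Five families are supported:
#'
#' \describe{
#'   \item{`uniform`}{All timepoints weighted equally (`1/T`); dynamic
#'     correlations reduce exactly to the static Pearson correlation.}
#'   \item{`dirac_delta`}{Weight 1 at timepoint `t`, 0 elsewhere
#'     (implemented exactly as a one-hot vector, not a narrow Gaussian).}
#'   \item{`gaussian`}{Weights fall off as a Gaussian density centred on
#'     `t`; `width` is the variance \eqn{\sigma^2} (in samples squared).}
#'   \item{`laplace`}{Weights fall off as a Laplace density centred on
#'     `t`; `width` is the scale \eqn{b} (in samples).}
#'   \item{`mexican_hat`}{Ricker wavelet centred on `t`; `width` is the
#'     wavelet scale \eqn{\sigma} (in samples). Negative side lobes flank
#'     the positive central peak, so the weighted "mean" is a
#'     local-versus-surround contrast.}
#' }
#'
#' Weights are evaluated on the observed range `1..T`, truncated, and
#' renormalized: non-negative families are scaled so the weights sum to 1
#' (edge timepoints therefore receive renormalized one-sided windows);
#' the Mexican hat is scaled so the *absolute* weights sum to 1, because
#' its raw weights sum to approximately zero at interior timepoints and
#' dividing by that sum would amplify the weights without bound.
#'
#' @param family One of `"uniform"`, `"dirac_delta"`, `"gaussian"`,
#'   `"laplace"`, `"mexican_hat"`.
#' @param width Positive width parameter (ignored for `uniform` and
#'   `dirac_delta`; see Details for the meaning per family).
#' @return An object of class `"kernel_spec"`.
#' @examples
#' k <- laplace_kernel(20)
#' w <- kernel_weights(k, t = 50, T = 100)
#' sum(w)  # 1
#' @seealso [kernel_weights()], [kernel_matrix()], [default_kernel_bank()]
#' @export
kernel_spec <- function(family = c("uniform", "dirac_delta", "gaussian",
                                   "laplace", "mexican_hat"),
                        width = NULL) {
  family <- match.arg(family)
  needs_width <- family %in% c("gaussian", "laplace", "mexican_hat")
  if (needs_width) {
    if (is.null(width) || !is.numeric(width) || length(width) != 1L ||
        !is.finite(width) || width <= 0) {
      stop("kernel family '", family, "' requires a positive numeric width",
           call. = FALSE)
    }
  } else {
    width <- NA_real_
  }
  structure(list(family = family, width = as.numeric(width)),
            class = "kernel_spec")
}

#' @rdname kernel_spec
#' @export
uniform_kernel <- function() kernel_spec("uniform")

#' @rdname kernel_spec
#' @export
dirac_kernel <- function() kernel_spec("dirac_delta")

#' @rdname kernel_spec
#' @export
gaussian_kernel <- function(width) kernel_spec("gaussian", width)

#' @rdname kernel_spec
#' @export
laplace_kernel <- function(width) kernel_spec("laplace", width)

#' @rdname kernel_spec
#' @export
mexican_hat_kernel <- function(width) kernel_spec("mexican_hat", width)

#' @export
print.kernel_spec <- function(x, ...) {
  if (is.na(x$width)) {
    cat("<kernel:", x$family, ">\n")
  } else {
    cat("<kernel:", x$family, "width", format(x$width), ">\n")
  }
  invisible(x)
}

#' @export
format.kernel_spec <- function(x, ...) {
  if (is.na(x$width)) x$family else paste0(x$family, "(", format(x$width), ")")
}

raw_kernel <- function(spec, t, T) {
  tau <- seq_len(T)
  switch(spec$family,
    uniform     = rep(1, T),
    dirac_delta = as.numeric(tau == t),
    gaussian    = exp(-(tau - t)^2 / (2 * spec$width)),
    laplace     = exp(-abs(tau - t) / spec$width),
    mexican_hat = {
      u <- (tau - t) / spec$width
      (1 - u^2) * exp(-u^2 / 2)
    })
}

#' Evaluate kernel weights at one timepoint
#'
#' Returns the length-`T` weight vector \eqn{\kappa_t(\tau)} for the
#' kernel centred at timepoint `t` (1-based), truncated to the observed
#' range and renormalized (see [kernel_spec()] for the normalization per
#' family).
#'
#' @param spec A [kernel_spec()].
#' @param t Centre timepoint, `1 <= t <= T`.
#' @param T Series length (`T >= 1`).
#' @return Numeric vector of length `T`.
#' @export
kernel_weights <- function(spec, t, T) {
  stopifnot(inherits(spec, "kernel_spec"))
  T <- as.integer(T)
  if (length(T) != 1L || is.na(T) || T < 1L)
    stop("series length T must be a positive integer", call. = FALSE)
  t <- as.integer(t)
  if (length(t) != 1L || is.na(t) || t < 1L || t > T)
    stop("timepoint t must lie in 1..T", call. = FALSE)
  w <- raw_kernel(spec, t, T)
  if (spec$family == "mexican_hat") {
    s <- sum(abs(w))
    if (s < 1e-8)
      stop("mexican_hat weights vanish over the observed range", call. = FALSE)
    w / s
  } else {
    w / sum(w)
  }
}

#' Kernel weight matrix for a whole series
#'
#' Stacks [kernel_weights()] for every centre timepoint: row `t` holds
#' \eqn{\kappa_t(\tau)}, \eqn{\tau = 1..T}.
#'
#' @inheritParams kernel_weights
#' @return A `T x T` matrix whose rows sum to 1 (absolute sum 1 for the
#'   Mexican hat).
#' @export
kernel_matrix <- function(spec, T) {
  t(vapply(seq_len(T), function(t) kernel_weights(spec, t, T),
           numeric(T)))
}

#' Default analysis kernel bank
#'
#' The bank used for robustness averaging in the temporal decoding
#' analyses: Gaussian, Laplace and Mexican hat kernels crossed with
#' widths 5, 10, 20 and 50 samples.
#'
#' @return A list of 12 [kernel_spec()] objects.
#' @export
default_kernel_bank <- function() {
  fams <- c("gaussian", "laplace", "mexican_hat")
  widths <- c(5, 10, 20, 50)
  bank <- list()
  for (f in fams) for (w in widths)
    bank[[paste0(f, "_", w)]] <- kernel_spec(f, w)
  bank
}
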