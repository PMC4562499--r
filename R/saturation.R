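#' Discovery counts over random library subsets
#'
#' For each subset size, draws `n_rep` seeded random subsets of the
#' libraries without replacement and counts the transcripts detected
#' (at least one mapped read) in at least one library of the subset.
#'
#' @param detections tibble `transcript`, `library`, `count` (reads
#'   mapped per library), or a logical/numeric detection matrix with
#'   transcripts in rows and libraries in columns.
#' @param sizes integer vector of subset sizes (each <= number of
#'   libraries).
#' @param n_rep replicates per size.
#' @param seed integer seed.
#' @return tibble `size`, `replicate`, `discovered`.
#' @export
subsample_discovery <- function(detections, sizes, n_rep = 10, seed = 0) {
  if (is.matrix(detections)) {
    det <- detections > 0
  } else {
    det <- detections %>%
      mutate(hit = .data$count > 0) %>%
      tidyr::pivot_wider(id_cols = "transcript", names_from = "library",
                         values_from = "hit", values_fill = FALSE)
    det <- as.matrix(det[, -1, drop = FALSE])
  }
  n_lib <- ncol(det)
  assert_that(all(sizes <= n_lib),
              "subset sizes cannot exceed the number of libraries")
  with_seed(derive_seed(seed, "saturation"), {
    purrr::map_dfr(sizes, function(sz) {
      purrr::map_dfr(seq_len(n_rep), function(rep) {
        if (sz == 0) {
          disc <- 0L
        } else {
          pick <- sample.int(n_lib, sz)
          disc <- sum(rowSums(det[, pick, drop = FALSE]) > 0)
        }
        tibble(size = sz, replicate = rep, discovered = as.integer(disc))
      })
    })
  })
}

#' Fit the one-site binding saturation curve
#'
#' Least-squares fit of `Y = Bmax * X / (Kd + X)`, the saturating
#' hyperbola used to model the number of discovered transcripts as a
#' function of sample count: `Bmax` is the asymptotic transcript count
#' and `Kd` the sample count at half saturation. Levenberg-Marquardt
#' optimization with deterministic initialization (`Bmax0 = max(Y)`,
#' `Kd0 = median(X)`) and a 1e-10 parameter tolerance. A constant `Y`
#' (degenerate boundary `Kd -> 0`) is flagged rather than fit.
#'
#' @param X sample counts (>= 3 distinct values).
#' @param Y mean discovered counts.
#' @return object of class `one_site_fit`: list with `Bmax`, `Kd`, `rss`,
#'   `degenerate`, `data`, and the underlying `fit` object.
#' @export
fit_one_site <- function(X, Y) {
  assert_that(length(X) == length(Y), "X and Y must have equal length")
  assert_that(length(unique(X)) >= 3, "need at least 3 distinct X values")
  dat <- tibble(X = as.numeric(X), Y = as.numeric(Y))
  if (stats::sd(dat$Y) < 1e-12) {
    return(structure(list(Bmax = mean(dat$Y), Kd = 0, rss = 0,
                          degenerate = TRUE, data = dat, fit = NULL),
                     class = "one_site_fit"))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(Y ~ Bmax * X / (Kd + X), data = dat,
                      start = list(Bmax = max(dat$Y), Kd = median(dat$X)),
                      lower = c(Bmax = 0, Kd = 0),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) stop("one-site fit failed to converge: ",
                             conditionMessage(e), call. = FALSE))
  cf <- coef(fit)
  structure(list(Bmax = unname(cf["Bmax"]), Kd = unname(cf["Kd"]),
                 rss = sum(resid(fit)^2),
                 degenerate = unname(cf["Kd"]) < 1e-8,
                 data = dat, fit = fit),
            class = "one_site_fit")
}

#' @export
print.one_site_fit <- function(x, ...) {
  cat("<one_site_fit> Y = Bmax * X / (Kd + X)\n")
  cat(sprintf("  Bmax = %.4g, Kd = %.4g, RSS = %.4g%s\n", x$Bmax, x$Kd,
              x$rss, if (x$degenerate) "  [degenerate: Kd at boundary]"
              else ""))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a one-site saturation fit
#'
#' @param x a `one_site_fit`.
#' @param ... unused.
#' @return one row per parameter (`term`, `estimate`, `std.error`).
#' @export
tidy.one_site_fit <- function(x, ...) {
  se <- if (!is.null(x$fit)) {
    sqrt(diag(stats::vcov(x$fit)))[c("Bmax", "Kd")]
  } else c(Bmax = NA_real_, Kd = NA_real_)
  tibble(term = c("Bmax", "Kd"),
         estimate = c(x$Bmax, x$Kd),
         std.error = unname(se))
}

#' @rdname tidy.one_site_fit
#' @return `glance()`: a one-row summary (`Bmax`, `Kd`, `rss`, `n`,
#'   `degenerate`).
#' @export
glance.one_site_fit <- function(x, ...) {
  tibble(Bmax = x$Bmax, Kd = x$Kd, rss = x$rss, n = nrow(x$data),
         degenerate = x$degenerate)
}

#' Predicted saturation curve
#'
#' @param object a `one_site_fit`.
#' @param newdata optional tibble with an `X` column.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.one_site_fit <- function(object, newdata = NULL, ...) {
  X <- (newdata %||% object$data)$X
  object$Bmax * X / (object$Kd + X)
}
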