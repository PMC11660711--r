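#' Model term specifications
#'
#' A term specification names one variable of a person-time table together
#' with its transformation in a model design matrix:
#'
#' * `"linear"` — the value as-is;
#' * `"quadratic"` — the value and its square (two columns);
#' * `"spline5"` — a natural cubic spline basis with 5 knots placed at the
#'   5th / 27.5th / 50th / 72.5th / 95th empirical percentiles of the
#'   fitting data (4 basis columns);
#' * `"categorical"` — `n_levels - 1` indicator columns against the lowest
#'   observed code as reference;
#' * `"interaction"` — the elementwise product with a second variable
#'   (`with`), labelled `"variable:with"`.
#'
#' @param variable column name.
#' @param transform one of `"linear"`, `"quadratic"`, `"spline5"`,
#'   `"categorical"`, `"interaction"`.
#' @param n_levels declared number of categories (categorical only, >= 2).
#' @param with second variable name (interaction only).
#' @param role `"baseline"` or `"time-varying"`; informational.
#' @return an object of class `term_spec`.
#' @export
term_spec <- function(variable,
                      transform = c("linear", "quadratic", "spline5",
                                    "categorical", "interaction"),
                      n_levels = NULL, with = NULL, role = "baseline") {
  transform <- match.arg(transform)
  if (transform == "categorical") {
    if (is.null(n_levels) || n_levels < 2) {
      stop_ppswitch("categorical terms need n_levels >= 2")
    }
  }
  if (transform == "interaction" && is.null(with)) {
    stop_ppswitch("interaction terms need a second variable ('with')")
  }
  structure(list(variable = variable, transform = transform,
                 n_levels = n_levels, with = with, role = role),
            class = "term_spec")
}

#' Compact term-list construction
#'
#' Builds a list of [term_spec()]s from name-value pairs: a character value
#' names the transformation, an integer declares a categorical term with
#' that many levels, e.g. `term_list(age = "linear", tdp = "quadratic",
#' ids = 4)`.
#'
#' @param ... named transformations.
#' @return list of `term_spec` objects.
#' @export
term_list <- function(...) {
  spec <- list(...)
  lapply(names(spec), function(v) {
    x <- spec[[v]]
    if (is.numeric(x)) term_spec(v, "categorical", n_levels = x)
    else term_spec(v, x)
  })
}

spline5_knots <- function(x) {
  qs <- stats::quantile(x, probs = c(0.05, 0.275, 0.50, 0.725, 0.95),
                        names = FALSE, type = 7)
  if (length(unique(qs)) < 5) {
    stop_ppswitch("spline5 term needs 5 distinct knot locations")
  }
  qs
}

#' Build a design-matrix reference from fitting data
#'
#' Freezes everything data-dependent about a term list (spline knots,
#' observed category codes) so the same columns can be reproduced exactly
#' at prediction time. Identical input yields byte-identical column labels
#' and values.
#'
#' @param data fitting data (person-time table or any data frame).
#' @param terms list of [term_spec()] objects.
#' @return an object of class `design_ref`.
#' @export
design_build <- function(data, terms) {
  refs <- lapply(terms, function(tm) {
    v <- tm$variable
    if (!v %in% names(data)) {
      stop_ppswitch(sprintf("design variable '%s' not found", v))
    }
    x <- data[[v]]
    if (tm$transform == "interaction" && !tm$with %in% names(data)) {
      stop_ppswitch(sprintf("design variable '%s' not found", tm$with))
    }
    if (tm$transform %in% c("linear", "quadratic", "spline5") &&
        !all(is.finite(x))) {
      stop_ppswitch(sprintf("design variable '%s' has non-finite values", v))
    }
    ref <- tm
    if (tm$transform == "spline5") {
      if (length(unique(x)) == 1) {
        stop_ppswitch(sprintf("constant column '%s' cannot carry a spline", v))
      }
      ref$knots <- spline5_knots(x)
    }
    if (tm$transform == "categorical") {
      lev <- sort(unique(x))
      if (any(!lev %in% seq_len(tm$n_levels))) {
        stop_ppswitch(sprintf(
          "variable '%s': category code outside 1..%d", v, tm$n_levels))
      }
      ref$levels <- lev
    }
    ref
  })
  structure(list(terms = refs), class = "design_ref")
}

#' Evaluate a design reference on (new) data
#'
#' @param ref a `design_ref` from [design_build()].
#' @param data data frame carrying the referenced variables.
#' @return numeric matrix with deterministic column labels (no intercept).
#' @export
design_matrix <- function(ref, data) {
  blocks <- lapply(ref$terms, function(tm) {
    v <- tm$variable
    if (!v %in% names(data)) {
      stop_ppswitch(sprintf("design variable '%s' not found", v))
    }
    x <- data[[v]]
    switch(tm$transform,
      linear = {
        m <- matrix(as.numeric(x), ncol = 1)
        colnames(m) <- v
        m
      },
      interaction = {
        if (!tm$with %in% names(data)) {
          stop_ppswitch(sprintf("design variable '%s' not found", tm$with))
        }
        m <- matrix(as.numeric(x) * as.numeric(data[[tm$with]]), ncol = 1)
        colnames(m) <- paste0(v, ":", tm$with)
        m
      },
      quadratic = {
        m <- cbind(as.numeric(x), as.numeric(x)^2)
        colnames(m) <- c(v, paste0(v, "^2"))
        m
      },
      spline5 = {
        b <- splines::ns(x, knots = tm$knots[2:4],
                         Boundary.knots = tm$knots[c(1, 5)])
        m <- unclass(b)[, , drop = FALSE]
        colnames(m) <- paste0(v, ".s", seq_len(ncol(m)))
        m
      },
      categorical = {
        unseen <- setdiff(unique(x), tm$levels)
        if (length(unseen)) {
          stop_ppswitch(sprintf(
            "variable '%s': unseen category code %s at prediction time",
            v, paste(unseen, collapse = ", ")))
        }
        lev <- tm$levels
        m <- sapply(lev[-1], function(l) as.numeric(x == l))
        m <- matrix(m, nrow = length(x))
        colnames(m) <- paste0(v, ".", lev[-1])
        m
      })
  })
  do.call(cbind, blocks)
}
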