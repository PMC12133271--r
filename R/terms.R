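#' Term specifications for imputation-model design matrices
#'
#' A term is the rowwise product of one or more (possibly powered) base
#' variables: `term_spec("x")` is the linear term `x`,
#' `term_spec("z", 3)` is `z^3`, and `term_spec(c("z", "edu"), c(3, 1))`
#' is the multiplicative term `z^3 * edu`. Terms are the building blocks of
#' [build_design()] and of [model_spec()] conditional models, and support
#' the polynomial/interaction imputation models used when a variable's
#' relationship with its predictors is nonlinear.
#'
#' @param vars character vector of base variable names (at least one).
#' @param powers integer powers, one per variable (default all 1).
#' @return an object of class `term_spec`.
#' @seealso [parse_terms()] for a compact string syntax.
#' @export
term_spec <- function(vars, powers = NULL) {
  if (!is.character(vars) || length(vars) < 1 || any(!nzchar(vars))) {
    stop("a term needs at least one named base variable", call. = FALSE)
  }
  if (is.null(powers)) powers <- rep(1L, length(vars))
  if (length(powers) != length(vars) || any(powers < 1) ||
      any(powers != round(powers))) {
    stop("`powers` must be positive integers, one per variable",
         call. = FALSE)
  }
  structure(list(vars = vars, powers = as.integer(powers)),
            class = "term_spec")
}

.term_label <- function(t) {
  paste0(ifelse(t$powers > 1, paste0(t$vars, "^", t$powers), t$vars),
         collapse = "*")
}

#' Parse compact term strings
#'
#' Each element of `text` describes one term: factors separated by `*` (or
#' `:`), each factor a variable name optionally raised to an integer power
#' with `^`. For example `c("x", "z^3", "z^3*edu")`.
#'
#' @param text character vector of term strings.
#' @return a list of [term_spec()] objects.
#' @examples
#' parse_terms(c("x", "z^3*edu"))
#' @export
parse_terms <- function(text) {
  lapply(text, function(s) {
    factors <- strsplit(gsub(" ", "", s), "[*:]", perl = TRUE)[[1]]
    if (!length(factors)) stop(sprintf("cannot parse term '%s'", s),
                               call. = FALSE)
    vars <- character(0); powers <- integer(0)
    for (f in factors) {
      parts <- strsplit(f, "^", fixed = TRUE)[[1]]
      has_caret <- grepl("^", f, fixed = TRUE)
      if (!length(parts) || !nzchar(parts[1]) ||
          (has_caret && length(parts) != 2) || length(parts) > 2) {
        stop(sprintf("cannot parse term '%s'", s), call. = FALSE)
      }
      p <- if (length(parts) == 2) suppressWarnings(as.integer(parts[2])) else 1L
      if (is.na(p) || p < 1) {
        stop(sprintf("cannot parse power in term '%s'", s), call. = FALSE)
      }
      vars <- c(vars, parts[1]); powers <- c(powers, p)
    }
    term_spec(vars, powers)
  })
}

#' Conditional imputation model specification
#'
#' Declares the conditional model for one incomplete variable: the target
#' and its predictor terms. An intercept is always included implicitly.
#' The target may not appear among its own predictors.
#'
#' @param target name of the variable to impute.
#' @param terms a list of [term_spec()] objects, or a character vector in
#'   [parse_terms()] syntax.
#' @return an object of class `model_spec`.
#' @examples
#' model_spec("y", c("x", "z"))        # p(y | x, z)
#' model_spec("z", c("y", "x", "w"))   # p(z | y, x, w)
#' @export
model_spec <- function(target, terms) {
  if (!is.character(target) || length(target) != 1 || !nzchar(target)) {
    stop("`target` must be a single variable name", call. = FALSE)
  }
  if (is.character(terms)) terms <- parse_terms(terms)
  if (inherits(terms, "term_spec")) terms <- list(terms)
  if (!is.list(terms) ||
      !all(vapply(terms, inherits, logical(1), "term_spec"))) {
    stop("`terms` must be term_spec objects or term strings", call. = FALSE)
  }
  pred <- unique(unlist(lapply(terms, `[[`, "vars")))
  if (target %in% pred) {
    stop(sprintf("target '%s' appears among its own predictor terms",
                 target), call. = FALSE)
  }
  structure(list(target = target, terms = terms), class = "model_spec")
}

#' Build a design matrix from term specifications
#'
#' Column 1 is the intercept; column `j + 1` is the rowwise product of the
#' powered base variables of term `j`, in the order the terms are listed.
#' An empty term list yields the intercept-only design.
#'
#' @param data a data.frame or named list of equal-length numeric vectors;
#'   all term variables must be present and complete.
#' @param terms a list of [term_spec()] objects (or a character vector,
#'   parsed with [parse_terms()]).
#' @return a numeric matrix with a leading `"(Intercept)"` column.
#' @examples
#' build_design(data.frame(x = 1:3), list(term_spec("x")))
#' @export
build_design <- function(data, terms) {
  if (is.character(terms)) terms <- parse_terms(terms)
  if (inherits(terms, "term_spec")) terms <- list(terms)
  n <- if (is.data.frame(data)) nrow(data) else length(data[[1]])
  X <- matrix(1, n, length(terms) + 1)
  labels <- "(Intercept)"
  j <- 1L
  for (t in terms) {
    j <- j + 1L
    col <- rep(1, n)
    for (k in seq_along(t$vars)) {
      v <- data[[t$vars[k]]]
      if (is.null(v)) {
        stop(sprintf("unknown variable '%s' in term specification",
                     t$vars[k]), call. = FALSE)
      }
      if (anyNA(v)) {
        stop(sprintf("missing values in term variable '%s'", t$vars[k]),
             call. = FALSE)
      }
      col <- col * v^t$powers[k]
    }
    X[, j] <- col
    labels <- c(labels, .term_label(t))
  }
  colnames(X) <- labels
  X
}
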