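#' Atomic propositions over state valuations
#'
#' An atomic proposition is a named, deterministic boolean predicate of a
#' state valuation (a one-row list/data.frame of variable values).  A
#' proposition set plays the role of the labeling function of a Markov
#' chain: each trace state is labeled with exactly the propositions whose
#' predicate holds on its valuation.
#'
#' @param name identifier string, unique within a model's registry.
#' @param predicate function taking a named list of variable values and
#'   returning a single logical.
#' @return an object of class `"smc_prop"`.
#' @examples
#' inflamed <- proposition("I", function(s) s$pro > 5)
#' @export
proposition <- function(name, predicate) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "smc_prop")
}

#' @export
print.smc_prop <- function(x, ...) {
  cat("atomic proposition", x$name, "\n")
  invisible(x)
}

check_prop_registry <- function(props) {
  if (is.null(props)) return(list())
  stopifnot(is.list(props))
  nm <- vapply(props, function(p) p$name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate proposition names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  names(props) <- nm
  props
}

#' Finite execution traces
#'
#' A trace is an ordered, finite sequence of states.  Each state carries a
#' variable valuation (one row of `values`) and the set of atomic
#' propositions holding there (one row of the logical `labels` matrix,
#' computed from `props` on construction).
#'
#' @param values a data.frame, one row per time step (step 0 first).
#' @param props list of [proposition()] objects used to label each state;
#'   may be empty.
#' @param meta optional named list (model id, parameter point, seed).
#' @return an object of class `"smc_trace"`.
#' @export
smc_trace <- function(values, props = list(), meta = list()) {
  values <- as.data.frame(values)
  if (nrow(values) < 1L) stop("a trace needs at least one state", call. = FALSE)
  props <- check_prop_registry(props)
  labels <- matrix(FALSE, nrow(values), length(props),
                   dimnames = list(NULL, names(props)))
  for (p in props) {
    labels[, p$name] <- vapply(seq_len(nrow(values)), function(i)
      isTRUE(p$predicate(as.list(values[i, , drop = FALSE]))), logical(1))
  }
  structure(list(values = values, labels = labels, meta = meta),
            class = "smc_trace")
}

## trace from a precomputed logical label matrix (no valuations needed);
## convenient for exhaustive monitor tests
trace_from_labels <- function(labels) {
  labels <- as.matrix(labels)
  storage.mode(labels) <- "logical"
  structure(list(values = data.frame(step = seq_len(nrow(labels)) - 1L),
                 labels = labels, meta = list()),
            class = "smc_trace")
}

trace_length <- function(trace) nrow(trace$values)

#' @export
print.smc_trace <- function(x, ...) {
  cat("execution trace:", trace_length(x), "states,",
      ncol(x$labels), "labeled propositions\n")
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.smc_trace <- function(x, ...) {
  cbind(step = seq_len(trace_length(x)) - 1L, x$values,
        as.data.frame(x$labels))
}

#' Plot trace observables over time
#'
#' @param x an `"smc_trace"`.
#' @param vars variables to draw; default all numeric columns.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.smc_trace <- function(x, vars = NULL, ...) {
  num <- vapply(x$values, is.numeric, logical(1))
  if (is.null(vars)) vars <- setdiff(names(x$values)[num], "step")
  m <- as.matrix(x$values[, vars, drop = FALSE])
  graphics::matplot(seq_len(nrow(m)) - 1L, m, type = "l", lty = 1,
                    xlab = "step", ylab = "level", ...)
  graphics::legend("topright", legend = vars, col = seq_along(vars),
                   lty = 1, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write / read traces as CSV
#'
#' The on-disk format has a `step` column followed by one column per
#' variable; labels are recomputed on load from the supplied propositions.
#'
#' @param trace an `"smc_trace"`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- cbind(step = seq_len(trace_length(trace)) - 1L, trace$values)
  df$step <- seq_len(nrow(df)) - 1L   # single authoritative step column
  df <- df[, !duplicated(names(df)), drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @param props propositions used to relabel the loaded states.
#' @export
read_trace_csv <- function(path, props = list()) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"step" %in% names(df))
    stop("trace CSV must have a 'step' header column", call. = FALSE)
  smc_trace(df[, setdiff(names(df), "step"), drop = FALSE], props = props)
}

#' Does a trace satisfy a formula?
#'
#' Convenience wrapper for [bltl_eval()] at position 0: the usual notion
#' of a sampled execution satisfying a monitored specification.
#'
#' @inheritParams bltl_eval
#' @return `TRUE` or `FALSE`.
#' @export
satisfies <- function(trace, formula) bltl_eval(trace, formula, 0L)
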