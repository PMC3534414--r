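`%||%` <- function(a, b) if (is.null(a)) b else a

# semicolon-joined set attributes on graph edges
split_semi <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- unlist(strsplit(x[!is.na(x)], ";", fixed = TRUE), use.names = FALSE)
  out[nzchar(out)]
}

join_semi <- function(x) paste(sort(unique(x[nzchar(x)])), collapse = ";")

semi_union <- function(x) join_semi(split_semi(x))

# edge attribute combination rules shared by merge/undirect/fuse steps
edge_attr_comb <- function() {
  list(reactions = semi_union, enzymes = semi_union,
       reversible = function(x) any(as.logical(x)), "ignore")
}

stop_usage <- function(...) {
  stop(structure(class = c("metamod_usage_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_solver <- function(...) {
  stop(structure(class = c("metamod_solver_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_usage(name, " must be a single finite number")
}
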