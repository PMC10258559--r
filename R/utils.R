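# Internal helpers shared across modules.

# Canonical 2D hierarchy, outermost to innermost random level.  The
# condition label is a fixed effect, not a random level; replicate ids
# embed the condition so that level columns alone define unique paths.
MV_LEVELS_2D <- c("lab", "person", "experiment", "replicate", "cell")
MV_KEY_COLS  <- c("lab", "person", "experiment", "condition", "replicate",
                  "cell", "time_min")

mv_stop <- function(msg, class = "migvar_error", call. = FALSE) {
  stop(structure(
    class = c(class, "migvar_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

mv_schema_stop <- function(msg) mv_stop(msg, class = "migvar_schema_error")

assert_columns <- function(table, cols, what = "table") {
  missing <- setdiff(cols, names(table))
  if (length(missing)) {
    mv_schema_stop(sprintf("%s is missing required column(s): %s",
                           what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    mv_stop(sprintf("`%s` must be a single integer >= %d", name, min),
            class = "migvar_parameter_error")
  }
  invisible(as.integer(x))
}

assert_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    mv_stop(sprintf("`%s` must be a single positive number", name),
            class = "migvar_parameter_error")
  }
  invisible(as.numeric(x))
}

# Deterministic 32-bit seed derivation so that every stage and unit of a
# run draws from an independent, reproducible stream.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (k in utf8ToInt(as.character(label))) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# Paste key columns into unit path ids; sep is unlikely to occur in labels.
path_id <- function(table, cols, sep = "\r") {
  if (length(cols) == 1L) as.character(table[[cols]])
  else do.call(paste, c(unname(as.list(table[cols])), list(sep = sep)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# non-standard-evaluation column names used in ggplot2 calls
utils::globalVariables(c("level", "variance", "set", "feature", "share"))
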