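# internal helpers shared across modules

CONTEXTS <- c("CG", "CHG", "CHH")
STATES <- c("u", "i", "m")

`%||%` <- rlang::`%||%`

# state labels <-> methylation level encoding (u=0, i=0.5, m=1)
state_to_level <- function(state) {
  unname(c(u = 0, i = 0.5, m = 1)[as.character(state)])
}

# deterministic float formatting for writers (byte-identical output)
fmt_num <- function(x, digits = 8) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# derive a child stream seed from a user seed; kept < 2^31
child_seed <- function(seed, k) {
  (as.integer(seed) * 48271L + as.integer(k)) %% 2147483399L
}
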