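# internal helpers shared across modules

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

stop_zd <- function(msg, class) {
  abort(msg, class = c(class, "zd_error"))
}

# percent values must live on the 0-100 scale everywhere in this package
check_percent <- function(x, what) {
  bad <- which(!is.na(x) & (x < 0 | x > 100))
  if (length(bad)) {
    stop_zd(
      sprintf(
        "%s outside [0, 100] at row%s %s (value%s %s)",
        what,
        if (length(bad) > 1) "s" else "",
        paste(head(bad, 5L), collapse = ", "),
        if (length(bad) > 1) "s" else "",
        paste(format(head(x[bad], 5L)), collapse = ", ")
      ),
      "zd_validation_error"
    )
  }
  invisible(x)
}
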