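# internal helpers shared across modules

# z-score a numeric vector; zero-variance input maps to all zeros
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# deterministic, order-independent 32-bit string hash (djb2), folded into
# [1, 2^31 - 2] so it can seed R's RNG on any platform
hash_seed <- function(..., master = 0L) {
  s <- paste(..., sep = "\r")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  h <- (h + as.numeric(master) * 2654435761) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

# run code under a local RNG seed without touching the caller's RNG stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# long (id, time, replicate, value) -> id x time matrix of replicate means
profile_matrix <- function(tbl, id_col, value_col) {
  wide <- tbl %>%
    dplyr::group_by(.data[[id_col]], .data$time) %>%
    dplyr::summarise(value = mean(.data[[value_col]]), .groups = "drop") %>%
    tidyr::pivot_wider(names_from = "time", values_from = "value") %>%
    dplyr::arrange(.data[[id_col]])
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[id_col]]
  m[, order(as.numeric(colnames(m))), drop = FALSE]
}

stopf <- function(fmt, ...) abort(sprintf(fmt, ...))
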