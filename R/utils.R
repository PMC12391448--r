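# shared helpers

# run code under a temporary RNG seed, restoring the caller's stream
with_seed_local <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

softmax2 <- function(logits) {
  m <- max(logits)
  e <- exp(logits - m)
  e / sum(e)
}

# log-softmax, numerically stable
log_softmax2 <- function(logits) {
  m <- max(logits)
  logits - m - log(sum(exp(logits - m)))
}

# split a data frame into a numeric feature matrix and integer labels
split_features_labels <- function(data, label_col = "label") {
  stopifnot(is.data.frame(data))
  if (!label_col %in% names(data)) {
    stop("data must contain a '", label_col, "' column", call. = FALSE)
  }
  y <- as.integer(data[[label_col]])
  if (any(!y %in% c(0L, 1L))) stop("labels must be 0/1", call. = FALSE)
  x <- as.matrix(data[setdiff(names(data), label_col)])
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  list(x = x, y = y)
}
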