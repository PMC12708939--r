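# Shared internal helpers.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' All 64 codons in alphabetical order
#' @return Character vector of length 64.
#' @export
all_codons <- function() {
  b <- c("A", "C", "G", "T")
  sort(do.call(paste0, expand.grid(b, b, b, stringsAsFactors = FALSE)))
}

#' The 61 sense codons (stops excluded) in alphabetical order
#' @return Character vector of length 61.
#' @export
sense_codons <- function() {
  setdiff(all_codons(), STOP_CODONS)
}

# Run `code` under a fixed RNG state when `seed` is given, without touching
# the caller's RNG otherwise.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Coerce a counts tibble (gene_id + numeric sample columns) or matrix to a
# numeric matrix with gene rownames.
counts_matrix <- function(counts) {
  if (is.matrix(counts)) {
    storage.mode(counts) <- "double"
    return(counts)
  }
  stopifnot(is.data.frame(counts))
  id_col <- if ("gene_id" %in% names(counts)) "gene_id" else names(counts)[1]
  m <- as.matrix(counts[setdiff(names(counts), id_col)])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(counts[[id_col]])
  m
}

# Row variances of a numeric matrix (sample variance; NA for < 2 columns).
row_var <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  (rowSums(x^2) - n * mu^2) / (n - 1)
}
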