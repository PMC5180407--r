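`%||%` <- function(a, b) if (is.null(a)) b else a

# Numeric -> string that survives a write/read round trip.
num_chr <- function(x) {
  out <- character(length(x))
  out[is.na(x)] <- "."
  ok <- !is.na(x)
  if (any(ok)) {
    s <- vapply(x[ok], function(v) {
      r <- format(v, digits = 15, scientific = FALSE, trim = TRUE)
      if (as.numeric(r) != v) r <- format(v, digits = 17, scientific = FALSE, trim = TRUE)
      r
    }, character(1))
    out[ok] <- s
  }
  out
}

chr_num <- function(x) {
  x[x == "." | x == ""] <- NA_character_
  as.numeric(x)
}

# Jaccard index between two interval sets (data.frames with chrom/start/end,
# 1-based closed coordinates).
#' Jaccard index between two interval sets
#'
#' Measures the base-pair overlap between two sets of genomic intervals
#' (e.g. called vs planted LOH segments) as intersection/union of covered
#' bases.
#'
#' @param x,y Data frames with columns `chrom`, `start`, `end` (1-based,
#'   closed intervals).
#' @return A single number in \[0, 1\]; 1 when both sets are empty.
#' @export
interval_jaccard <- function(x, y) {
  cover <- function(df) {
    if (is.null(df) || nrow(df) == 0) return(list())
    out <- list()
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      sub <- sub[order(sub$start), , drop = FALSE]
      merged <- list()
      cs <- sub$start[1]; ce <- sub$end[1]
      if (nrow(sub) > 1) {
        for (i in 2:nrow(sub)) {
          if (sub$start[i] <= ce + 1) ce <- max(ce, sub$end[i])
          else { merged[[length(merged) + 1L]] <- c(cs, ce); cs <- sub$start[i]; ce <- sub$end[i] }
        }
      }
      merged[[length(merged) + 1L]] <- c(cs, ce)
      out[[as.character(ch)]] <- merged
    }
    out
  }
  cx <- cover(x); cy <- cover(y)
  if (length(cx) == 0 && length(cy) == 0) return(1)
  bp <- function(iv) sum(vapply(iv, function(v) v[2] - v[1] + 1, numeric(1)))
  inter <- 0; total_x <- 0; total_y <- 0
  for (ch in union(names(cx), names(cy))) {
    ix <- cx[[ch]] %||% list(); iy <- cy[[ch]] %||% list()
    total_x <- total_x + if (length(ix)) bp(ix) else 0
    total_y <- total_y + if (length(iy)) bp(iy) else 0
    for (a in ix) for (b in iy) {
      lo <- max(a[1], b[1]); hi <- min(a[2], b[2])
      if (hi >= lo) inter <- inter + (hi - lo + 1)
    }
  }
  un <- total_x + total_y - inter
  if (un == 0) return(1)
  inter / un
}

read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  sort(unique(x))
}

read_tsv_file <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, comment.char = "#",
                    quote = "", na.strings = c("NA"), ...)
}
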