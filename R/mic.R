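# Maximal information coefficient: grid-search normalized mutual information
# over axis partitions with the B(n) = n^alpha grid-size bound.

.bin_axis <- function(x, nbins, scheme) {
  if (scheme == "freq") {
    br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nbins + 1),
                                 type = 7, names = FALSE))
  } else {
    br <- seq(min(x), max(x), length.out = nbins + 1)
    br <- unique(br)
  }
  if (length(br) < 3) return(NULL)
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

.mutual_info_bits <- function(xb, yb) {
  tb <- table(xb, yb)
  n <- sum(tb)
  p <- tb / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Maximal information coefficient
#'
#' Estimates the MIC of two numeric vectors: the maximum, over grid
#' partitions (a x b cells, a*b <= B(n) = n^alpha), of the mutual
#' information of the gridded variables normalized by `log2(min(a, b))`.
#' Candidate partitions are equal-frequency and equal-width binnings of each
#' axis. The estimate lies in \[0, 1\]: near 1 for noiseless functional
#' relationships (including non-monotone ones invisible to Pearson r), near
#' 0 under independence.
#'
#' @param x,y Numeric vectors of equal length (>= 20 after NA removal).
#' @param alpha Grid-bound exponent, `B(n) = n^alpha` (default 0.6).
#' @return MIC estimate in \[0, 1\]. A constant input yields 0 with a warning.
#' @export
mic <- function(x, y, alpha = 0.6) {
  ok <- !(is.na(x) | is.na(y))
  x <- as.numeric(x[ok]); y <- as.numeric(y[ok])
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 20) stop("mic requires at least 20 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; MIC set to 0")
    return(0)
  }
  B <- max(4, floor(n^alpha))
  k_max <- max(2, floor(B / 2))
  bins_of <- function(v) {
    lapply(seq_len(k_max), function(k) {
      if (k < 2) return(list())
      out <- list(.bin_axis(v, k, "freq"), .bin_axis(v, k, "width"))
      out[!vapply(out, is.null, logical(1))]
    })
  }
  xbins <- bins_of(x)
  ybins <- bins_of(y)
  best <- 0
  for (a in 2:k_max) {
    b_max <- floor(B / a)
    if (b_max < 2) break
    for (b in 2:b_max) {
      for (xb in xbins[[a]]) {
        for (yb in ybins[[b]]) {
          na <- length(unique(xb)); nb <- length(unique(yb))
          if (na < 2 || nb < 2) next
          val <- .mutual_info_bits(xb, yb) / log2(min(na, nb))
          if (val > best) best <- val
        }
      }
    }
  }
  min(best, 1)
}
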