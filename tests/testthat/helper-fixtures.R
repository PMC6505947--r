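# shared fixture builders; everything is generated in code, no data files

toy_table <- function() {
  otu_table(matrix(c(1L, 2L, 3L, 4L, 5L, 6L), 2, 3, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("Otu1", "Otu2", "Otu3"))))
}

random_table <- function(n = 5, t = 8, lambda = 10, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * t, lambda), n, t,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("Otu%03d", seq_len(t))))
  otu_table(m)
}

toy_metadata <- function(n_per = c(7, 6, 7, 5), ids = NULL) {
  n <- sum(n_per)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(n))
  sample_metadata(ids,
                  rep(c("chinstrap", "chinstrap", "gentoo", "gentoo"), n_per),
                  rep(c("feeding", "moulting", "feeding", "moulting"), n_per))
}

toy_tree <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

star_tree <- function(n = 4) {
  ape::read.tree(text = paste0("(", paste0(LETTERS[seq_len(n)], ":1",
                                           collapse = ","), ");"))
}

# brute-force betaMNTD straight from the definition, nested loops
bmntd_oracle <- function(x_i, x_j, td, weighted = TRUE) {
  pi <- which(x_i > 0); pj <- which(x_j > 0)
  mins_i <- sapply(pi, function(t) min(sapply(pj, function(u) td[t, u])))
  mins_j <- sapply(pj, function(u) min(sapply(pi, function(t) td[u, t])))
  if (weighted) {
    wi <- x_i[pi] / sum(x_i[pi]); wj <- x_j[pj] / sum(x_j[pj])
  } else {
    wi <- rep(1 / length(pi), length(pi))
    wj <- rep(1 / length(pj), length(pj))
  }
  0.5 * (sum(wi * mins_i) + sum(wj * mins_j))
}

# naive double-loop Bray-Curtis
bray_oracle <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(abs(m[i, ] - m[j, ])) / sum(m[i, ] + m[j, ])
  }
  d
}
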