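# Fixtures are built in code: a minimal community, hand-made sample
# chemistry, and an independent brute-force CART split oracle.

tiny_community <- function() {
  counts <- matrix(c(5L, 0L, 3L,
                     2L, 7L, 0L), nrow = 3,
                   dimnames = list(c("otu1", "otu2", "otu3"), c("s1", "s2")))
  taxonomy <- data.frame(
    taxon_id = c("otu1", "otu2", "otu3"),
    lineage = c("d__Bacteria; p__P1; c__C1; o__O1; f__FamA",
                "d__Bacteria; p__P1; c__C1; o__O1; f__FamA",
                "d__Bacteria; p__P2; c__C2"),
    stringsAsFactors = FALSE)
  metadata <- data.frame(sample_id = c("s1", "s2"),
                         core_id = c("c1", "c1"), area_id = c("A", "A"),
                         depth_cm = c(10, 50), stringsAsFactors = FALSE)
  community_table(counts, taxonomy, metadata)
}

# One sample_chemistry row per call site; flags default to usable values.
make_chem <- function(O2 = NA, NO3 = NA, NH4 = NA, Mn = NA,
                      O2_flag = NULL, n = length(O2)) {
  len <- max(length(O2), length(NO3), length(NH4), length(Mn))
  df <- data.frame(sample_id = sprintf("s%02d", seq_len(len)),
                   core_id = "c1", depth_cm = seq_len(len) * 10,
                   stringsAsFactors = FALSE)
  for (con in c("O2", "NO3", "NH4", "Mn")) {
    vals <- rep_len(get(con), len)
    df[[con]] <- vals
    df[[paste0(con, "_flag")]] <- ifelse(is.na(vals), "unavailable",
                                         "interpolated")
  }
  if (!is.null(O2_flag)) df$O2_flag <- rep_len(O2_flag, len)
  class(df) <- c("sample_chemistry", "data.frame")
  df
}

# Independent exhaustive split oracle: direct impurity evaluation for
# every feature and every midpoint between consecutive distinct values.
brute_best_split <- function(X, y, criterion = "sse", min_leaf = 1) {
  imp <- function(yy) {
    if (criterion == "sse") return(sum((yy - mean(yy))^2))
    p <- c(mean(yy == 0), mean(yy == 1))
    1 - sum(p^2)
  }
  n <- nrow(X)
  parent <- imp(y)
  tie_tol <- 1e-9 * (abs(parent) + 1) # same documented tie rule
  best <- NULL
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    for (t in (xs[-length(xs)] + xs[-1]) / 2) {
      left <- X[, j] <= t
      if (sum(left) < min_leaf || sum(!left) < min_leaf) next
      child <- if (criterion == "sse") imp(y[left]) + imp(y[!left])
               else (sum(left) * imp(y[left]) + sum(!left) * imp(y[!left])) / n
      gain <- parent - child
      if (is.null(best) || gain > best$gain + tie_tol)
        best <- list(feature = j, threshold = t, gain = gain)
    }
  }
  if (is.null(best) || best$gain <= 0) return(NULL)
  best
}

random_split_instance <- function(seed, max_n = 10, max_p = 4) {
  set.seed(seed)
  n <- sample(4:max_n, 1)
  p <- sample(1:max_p, 1)
  list(X = matrix(runif(n * p), n, p), y = rnorm(n),
       y_cls = sample(0:1, n, replace = TRUE))
}
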