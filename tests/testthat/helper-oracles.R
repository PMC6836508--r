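# Brute-force oracles, kept deliberately independent of the package's
# implementations: O(n^2) pairwise predicates plus explicit transitive
# closure by breadth-first search.

bfs_components <- function(linked) {
  n <- nrow(linked)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    k <- k + 1L
    queue <- s
    while (length(queue)) {
      i <- queue[1]
      queue <- queue[-1]
      if (!is.na(comp[i])) next
      comp[i] <- k
      queue <- c(queue, which(linked[i, ] & is.na(comp)))
    }
  }
  comp
}

oracle_cluster <- function(adjs, window = 10) {
  n <- nrow(adjs)
  linked <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) { linked[i, j] <- TRUE; next }
    if (adjs$tool[i] != adjs$tool[j]) next
    ends_i <- list(c(adjs$chrom1[i], adjs$pos1[i]),
                   c(adjs$chrom2[i], adjs$pos2[i]))
    ends_j <- list(c(adjs$chrom1[j], adjs$pos1[j]),
                   c(adjs$chrom2[j], adjs$pos2[j]))
    for (a in ends_i) for (b in ends_j) {
      if (a[1] == b[1] &&
          abs(as.numeric(a[2]) - as.numeric(b[2])) <= window)
        linked[i, j] <- TRUE
    }
  }
  bfs_components(linked)
}

oracle_merge_components <- function(calls, cfg = merge_config()) {
  n <- nrow(calls)
  linked <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && mergeable(calls[i, ], calls[j, ], cfg))
      linked[i, j] <- TRUE
  }
  bfs_components(linked)
}

# canonical partition representation: sorted list of sorted member-id sets
partition_of <- function(ids, comp) {
  p <- lapply(split(ids, comp), sort)
  unname(p[order(vapply(p, `[`, "", 1))])
}

random_adjacencies <- function(n, n_chrom = 2, span = 5000, tools = "SIM") {
  chrom <- sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE))
  pos1 <- sample.int(span, n, replace = TRUE)
  len <- sample(50:500, n, replace = TRUE)
  adjacencies(chrom, pos1, sample(c("R", "L"), n, replace = TRUE),
              chrom, pos1 + len, sample(c("R", "L"), n, replace = TRUE),
              tool = sample(tools, n, replace = TRUE),
              id = sprintf("r%d", seq_len(n)))
}

random_calls <- function(n, n_chrom = 2, span = 50000) {
  type <- sample(c("DEL", "TDUP", "INS", "DDUP"), n, replace = TRUE)
  chrom <- sprintf("chr%d", sample.int(n_chrom, n, replace = TRUE))
  start <- sample.int(span, n, replace = TRUE)
  len <- sample(50:2000, n, replace = TRUE)
  ins_pos <- ifelse(type %in% c("INS", "DDUP"),
                    start + len + sample.int(span, n, replace = TRUE),
                    NA_real_)
  start[type == "INS"] <- ins_pos[type == "INS"]
  end <- ifelse(type == "INS", start, start + len)
  cnv_calls(type = type, chrom = chrom, start = start, end = end,
            ins_chrom = ifelse(is.na(ins_pos), NA_character_, chrom),
            ins_pos = ins_pos,
            pe_support = sample.int(20, n, replace = TRUE),
            sr_support = sample.int(20, n, replace = TRUE),
            source_tools = sample(c("DELLY", "GRIDSS", "LUMPY", "MANTA"), n,
                                  replace = TRUE),
            id = sprintf("c%d", seq_len(n)))
}

# a planted-signal labeled call set: label derived from caller concordance
# and support, optionally with flip noise
planted_call_set <- function(n, noise = 0, seed = 1) {
  withr::with_seed(seed, {
    calls <- random_calls(n, n_chrom = 5)
    calls$chrom <- sprintf("chr%d", sample.int(5, n, replace = TRUE))
    n_tools <- sample.int(4, n, replace = TRUE)
    calls$source_tools <- vapply(n_tools, function(k)
      paste(sort(sample(c("DELLY", "GRIDSS", "LUMPY", "MANTA"), k)),
            collapse = ","), character(1))
    labels <- as.integer(n_tools >= 3 |
                           (calls$pe_support + calls$sr_support) > 30)
    if (noise > 0) {
      flip <- runif(n) < noise
      labels[flip] <- 1L - labels[flip]
    }
    list(calls = calls, labels = labels)
  })
}
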