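# Independent oracles used to cross-check the package implementations.
# These deliberately re-derive each quantity by direct enumeration or brute
# force, sharing no code with the functions they check.

GC <- Biostrings::GENETIC_CODE
ORACLE_SENSE <- names(GC)[GC != "*"]

oracle_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in oracle_permutations(v[-i])) {
      out[[length(out) + 1L]] <- c(v[i], rest)
    }
  }
  out
}

# Synonymous site count of a codon by explicit neighbor enumeration.
oracle_sites <- function(codon) {
  cs <- strsplit(codon, "")[[1]]
  s <- 0
  for (pos in 1:3) {
    for (alt in setdiff(c("A", "C", "G", "T"), cs[pos])) {
      nb <- cs; nb[pos] <- alt
      nb <- paste(nb, collapse = "")
      if (GC[[nb]] != "*" && GC[[nb]] == GC[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

# Pathway-averaged (sd, nd) between two sense codons by explicit
# enumeration of every ordering of the differing positions.
oracle_pair_counts <- function(c1, c2) {
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  diffs <- which(a != b)
  if (length(diffs) == 0L) return(c(sd = 0, nd = 0))
  run <- function(skip_stops) {
    tot_sd <- 0; tot_nd <- 0; n_valid <- 0L
    for (ord in oracle_permutations(diffs)) {
      cur <- a
      sd <- 0; nd <- 0; valid <- TRUE
      for (pos in ord) {
        nxt <- cur; nxt[pos] <- b[pos]
        aa1 <- GC[[paste(cur, collapse = "")]]
        aa2 <- GC[[paste(nxt, collapse = "")]]
        if (aa2 == "*" && skip_stops) { valid <- FALSE; break }
        if (aa1 == aa2 && aa1 != "*") sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      if (valid) {
        tot_sd <- tot_sd + sd; tot_nd <- tot_nd + nd
        n_valid <- n_valid + 1L
      }
    }
    if (n_valid == 0L) return(NULL)
    c(sd = tot_sd / n_valid, nd = tot_nd / n_valid)
  }
  res <- run(skip_stops = TRUE)
  if (is.null(res)) res <- run(skip_stops = FALSE)
  res
}

# Complete-linkage merge heights by brute force over cluster partitions.
oracle_complete_linkage_heights <- function(mat) {
  d <- as.matrix(stats::dist(mat))
  clusters <- as.list(seq_len(nrow(mat)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- Inf; bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best) { best <- h; bi <- i; bj <- j }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# Net-charge grid scan for the isoelectric point (step 1e-4).
oracle_pi_grid <- function(residues, pka = c(Nterm = 8.6, Cterm = 3.6,
                                             C = 8.5, D = 3.9, E = 4.1,
                                             H = 6.5, K = 10.8, R = 12.5,
                                             Y = 10.1)) {
  cs <- strsplit(residues, "")[[1]]
  n <- function(a) sum(cs == a)
  grid <- seq(0, 14, by = 1e-4)
  q <- 1 / (1 + 10^(grid - pka["Nterm"])) +
    n("K") / (1 + 10^(grid - pka["K"])) +
    n("R") / (1 + 10^(grid - pka["R"])) +
    n("H") / (1 + 10^(grid - pka["H"])) -
    1 / (1 + 10^(pka["Cterm"] - grid)) -
    n("D") / (1 + 10^(pka["D"] - grid)) -
    n("E") / (1 + 10^(pka["E"] - grid)) -
    n("C") / (1 + 10^(pka["C"] - grid)) -
    n("Y") / (1 + 10^(pka["Y"] - grid))
  grid[which.min(abs(q))]
}

# Random annotated zipper built directly (not via the generator), for
# contact-enumeration checks.
random_annotation <- function(n_heptads, seed) {
  set.seed(seed)
  hs <- lapply(seq_len(n_heptads) - 1L, function(k) {
    res <- sample(setdiff(zipperscan:::AA_STANDARD, "P"), 7, replace = TRUE)
    names(res) <- c("a", "b", "c", "d", "e", "f", "g")
    list(index = k, residues = res)
  })
  structure(list(protein_id = paste0("rand", seed), n_pos = 1L, rk_pos = 9L,
                 anchor_pos = 13L, weak_anchor = FALSE, heptads = hs,
                 terminated_by = "end_of_sequence"),
            class = "zipper_annotation")
}

# Do a recovered annotation's registers equal the planted truth?
registers_equal <- function(a, b) {
  identical(a$anchor_pos, b$anchor_pos) &&
    length(a$heptads) == length(b$heptads) &&
    all(vapply(seq_along(a$heptads), function(i) {
      identical(a$heptads[[i]]$index, b$heptads[[i]]$index) &&
        identical(a$heptads[[i]]$residues, b$heptads[[i]]$residues)
    }, logical(1)))
}
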