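# Independent oracles the implementation is checked against. These stay
# deliberately naive: position-by-position scans, textbook recursions.

# IUPAC sets for the naive motif scan
iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                   R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
                   W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
                   B = c("C", "G", "T"), D = c("A", "G", "T"),
                   H = c("A", "C", "T"), V = c("A", "C", "G"),
                   N = c("A", "C", "G", "T"))

# 0-based motif start positions by brute-force scan; degeneracy expanded in
# the motif only
naive_motif_scan <- function(seq, motif) {
  n <- nchar(seq); m <- nchar(motif)
  if (n < m) return(integer(0))
  sc <- strsplit(seq, "")[[1]]
  mc <- strsplit(motif, "")[[1]]
  hits <- integer(0)
  for (p in 0:(n - m)) {
    ok <- TRUE
    for (j in seq_len(m)) {
      if (!sc[p + j] %in% iupac_sets[[mc[j]]]) { ok <- FALSE; break }
    }
    if (ok) hits <- c(hits, p)
  }
  hits
}

# additive relationship by the coancestry (kinship) recursion, memoised;
# an independent path-counting route to the same matrix
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  pos <- setNames(seq_len(n), ped$id)
  si <- pos[ped$sire]; di <- pos[ped$dam]
  memo <- new.env(hash = TRUE)
  phi <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- paste(min(i, j), max(i, j))
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (i == j) {
      0.5 * (1 + phi(si[i], di[i]))
    } else {
      # recurse on the later-born individual (parents precede offspring)
      a <- max(i, j); b <- min(i, j)
      0.5 * (phi(si[a], b) + phi(di[a], b))
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) {
    A[i, j] <- A[j, i] <- 2 * phi(i, j)
  }
  A
}

# random acyclic pedigree: animals numbered so parents always precede
random_pedigree <- function(n, p_known = 0.7) {
  sire <- dam <- rep(NA_character_, n)
  sex <- sample(c("male", "female"), n, replace = TRUE)
  ids <- sprintf("a%02d", seq_len(n))
  for (i in seq_len(n)) {
    if (i < 3) next
    males <- which(sex[seq_len(i - 1)] == "male")
    females <- which(sex[seq_len(i - 1)] == "female")
    if (length(males) && runif(1) < p_known)
      sire[i] <- ids[males[sample.int(length(males), 1)]]
    if (length(females) && runif(1) < p_known)
      dam[i] <- ids[females[sample.int(length(females), 1)]]
  }
  pedigree(data.frame(id = ids, sire = sire, dam = dam, sex = sex,
                      stringsAsFactors = FALSE))
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# small balanced record table for model tests: nb birds x m records each
balanced_records <- function(nb, m, bird_effect_sd = 0, resid_sd = 1,
                             mu = 10, genotype = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("b%03d", seq_len(nb))
  u <- rnorm(nb, 0, bird_effect_sd)
  if (is.null(genotype)) genotype <- sample(genotype_levels(), nb, replace = TRUE)
  rec <- data.frame(pigeon_id = rep(ids, each = m),
                    ap = mu + rep(u, each = m) + rnorm(nb * m, 0, resid_sd),
                    genotype = rep(genotype, each = m),
                    sex = "male", breeder = "A", weather_start = "sunny",
                    weather_end = "sunny", category = "short",
                    stringsAsFactors = FALSE)
  A <- diag(nb); dimnames(A) <- list(ids, ids)
  list(records = rec, A = A, ids = ids, u = u)
}
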