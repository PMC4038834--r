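## Independent oracles, coded separately from the package internals.
## Scoring model (shared definition): match/mismatch per aligned column,
## a gap run of length L costs gap_open + L * gap_extend, runs may abut.

random_seq <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

## Plain-R three-state affine DP, score only.
oracle_affine_score <- function(a, b, type = c("global", "local"),
                                match = 1, mismatch = -1,
                                gap_open = -2, gap_extend = -1) {
  type <- match.arg(type)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- matrix(NEG, n + 1, m + 1); Ia <- M; Ib <- M
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) Ia[i + 1, 1] <- gap_open + i * gap_extend
    for (j in seq_len(m)) Ib[1, j + 1] <- gap_open + j * gap_extend
  } else {
    M[, 1] <- 0; M[1, ] <- 0
  }
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    prev <- max(M[i, j], Ia[i, j], Ib[i, j])
    v <- if (prev < NEG / 2) NEG else s + prev
    if (type == "local") v <- max(0, v)
    M[i + 1, j + 1] <- v
    Ia[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_extend,
                            Ia[i, j + 1] + gap_extend,
                            Ib[i, j + 1] + gap_open + gap_extend)
    Ib[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_extend,
                            Ib[i + 1, j] + gap_extend,
                            Ia[i + 1, j] + gap_open + gap_extend)
  }
  if (type == "global") max(M[n + 1, m + 1], Ia[n + 1, m + 1], Ib[n + 1, m + 1])
  else max(0, max(M))
}

## Brute-force enumeration of all inverted repeats in the last `window`
## bases; returns NULL or the best under (max arm, min mismatches,
## rightmost right-arm end), as 0-based element-local coordinates.
oracle_hairpin <- function(s, window = 50, arm_min = 6, arm_max = 12,
                           loop_min = 2, loop_max = 8, max_mismatch = 1) {
  n <- nchar(s)
  w <- min(window, n)
  off <- n - w
  win <- strsplit(substr(s, off + 1, n), "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  best <- NULL
  for (i in seq_len(w)) for (arm in arm_min:arm_max) for (loop in loop_min:loop_max) {
    rend <- i + 2 * arm + loop - 1
    if (rend > w) next
    left <- win[i:(i + arm - 1)]
    right <- win[(i + arm + loop):rend]
    mm <- sum(left != unname(comp[rev(right)]), na.rm = FALSE)
    if (is.na(mm) || mm > max_mismatch) next
    key <- c(arm, -mm, rend)
    if (is.null(best) || key[1] > best$key[1] ||
        (key[1] == best$key[1] && (key[2] > best$key[2] ||
         (key[2] == best$key[2] && key[3] > best$key[3])))) {
      best <- list(key = key,
                   left_start = off + i - 1, right_start = off + i + arm + loop - 1,
                   arm = arm, loop = loop, mismatches = mm)
    }
  }
  best
}

## Direct evaluation of the TN93 closed form from site counts.
oracle_tn93 <- function(ca, cb) {
  n <- length(ca)
  freq <- table(factor(c(ca, cb), levels = c("A", "C", "G", "T"))) / (2 * n)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  P1 <- sum((ca == "A" & cb == "G") | (ca == "G" & cb == "A")) / n
  P2 <- sum((ca == "C" & cb == "T") | (ca == "T" & cb == "C")) / n
  Q <- sum(ca != cb) / n - P1 - P2
  a1 <- -log(1 - P1 * gR / (2 * gA * gG) - Q / (2 * gR))
  a2 <- -log(1 - P2 * gY / (2 * gC * gT) - Q / (2 * gY))
  b <- -log(1 - Q / (2 * gR * gY))
  (2 * gA * gG / gR) * (a1 - gY * b) +
    (2 * gC * gT / gY) * (a2 - gR * b) +
    2 * gR * gY * b
}

## Brute-force Dollo: enumerate every subset of loss edges inside the
## subtree rooted at each possible MRCA node once, recording the minimum
## subset size achieving each absent-tip set. pres: named logical over all
## tree tips (trees with <= 8 leaves).
oracle_dollo_maps <- function(tree) {
  nt <- length(tree$tip.label)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- i
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  parent_of <- function(x) {
    row <- which(tree$edge[, 2] == x)
    if (length(row)) tree$edge[row[1], 1] else NA_integer_
  }
  under <- function(x, anc) {
    p <- x
    repeat {
      if (is.na(p)) return(FALSE)
      if (p == anc) return(TRUE)
      p <- parent_of(p)
    }
  }
  maps <- list()
  for (v in (nt + 1L):(nt + tree$Nnode)) {
    allowed <- which(vapply(seq_len(nrow(tree$edge)), function(e)
      under(tree$edge[e, 1], v), logical(1)))
    k <- length(allowed)
    tipmask <- vapply(allowed, function(e) {
      tips <- desc[[tree$edge[e, 2]]]
      sum(bitwShiftL(1L, tips[tips <= nt] - 1L))
    }, numeric(1))
    ## subset DP over bitmasks: absent-set and popcount per subset
    nmask <- 2^k
    absent <- integer(nmask); losses <- integer(nmask)
    if (k > 0) for (mask in 1:(nmask - 1)) {
      low <- bitwAnd(mask, -mask)
      bit <- 1L + as.integer(round(log2(low)))
      rest <- mask - low
      absent[mask + 1L] <- bitwOr(absent[rest + 1L], as.integer(tipmask[bit]))
      losses[mask + 1L] <- losses[rest + 1L] + 1L
    }
    best <- rep(Inf, 2^nt)
    for (mask in seq_len(nmask) - 1L) {
      a <- absent[mask + 1L] + 1L
      if (losses[mask + 1L] < best[a]) best[a] <- losses[mask + 1L]
    }
    maps[[as.character(v)]] <- best
  }
  list(maps = maps, desc = desc, nt = nt)
}

oracle_dollo <- function(tree, pres, cache = NULL) {
  present <- names(pres)[pres]
  stopifnot(length(present) >= 1)
  if (length(present) <= 1 || all(pres)) return(0L)
  if (is.null(cache)) cache <- oracle_dollo_maps(tree)
  mrca <- ape::getMRCA(tree, present)
  in_mrca <- cache$desc[[mrca]]
  in_mrca <- in_mrca[in_mrca <= cache$nt]
  target <- sum(bitwShiftL(1L, setdiff(in_mrca, which(pres)) - 1L))
  as.integer(cache$maps[[as.character(mrca)]][target + 1L])
}

## Sum-of-pairs score of an MSA under a linear gap scheme (residue-gap = g,
## gap-gap = 0), used against the exhaustive 3-sequence DP.
sp_score <- function(rows, match = 1, mismatch = -1, g = -3) {
  m <- do.call(rbind, strsplit(rows, ""))
  tot <- 0
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    for (x in seq_len(nrow(m) - 1)) for (y in (x + 1):nrow(m)) {
      a <- col[x]; b <- col[y]
      tot <- tot + if (a == "-" && b == "-") 0
        else if (a == "-" || b == "-") g
        else if (a == b) match else mismatch
    }
  }
  tot
}

## Exhaustive 3-sequence sum-of-pairs DP (linear gaps), score only.
oracle_msa3 <- function(s1, s2, s3, match = 1, mismatch = -1, g = -3) {
  A <- strsplit(s1, "")[[1]]; B <- strsplit(s2, "")[[1]]; C <- strsplit(s3, "")[[1]]
  n1 <- length(A); n2 <- length(B); n3 <- length(C)
  sub <- function(a, b) if (a == b) match else mismatch
  D <- array(-Inf, dim = c(n1 + 1, n2 + 1, n3 + 1))
  D[1, 1, 1] <- 0
  for (i in 0:n1) for (j in 0:n2) for (k in 0:n3) {
    if (i + j + k == 0) next
    best <- -Inf
    if (i > 0 && j > 0 && k > 0)
      best <- max(best, D[i, j, k] + sub(A[i], B[j]) + sub(A[i], C[k]) +
                    sub(B[j], C[k]))
    if (i > 0 && j > 0)
      best <- max(best, D[i, j, k + 1] + sub(A[i], B[j]) + 2 * g)
    if (i > 0 && k > 0)
      best <- max(best, D[i, j + 1, k] + sub(A[i], C[k]) + 2 * g)
    if (j > 0 && k > 0)
      best <- max(best, D[i + 1, j, k] + sub(B[j], C[k]) + 2 * g)
    if (i > 0) best <- max(best, D[i, j + 1, k + 1] + 2 * g)
    if (j > 0) best <- max(best, D[i + 1, j, k + 1] + 2 * g)
    if (k > 0) best <- max(best, D[i + 1, j + 1, k] + 2 * g)
    D[i + 1, j + 1, k + 1] <- best
  }
  D[n1 + 1, n2 + 1, n3 + 1]
}

## Mutated copy helper (substitutions only, independent of the package).
mutate_oracle <- function(s, n_subs) {
  ch <- strsplit(s, "")[[1]]
  pos <- sample(length(ch), n_subs)
  for (i in pos) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

## Perfectly congruent alignment for a tree: `per_edge` identical columns
## supporting each internal bipartition plus one private site per tip.
congruent_alignment <- function(tree, per_edge = 25) {
  tips <- tree$tip.label
  rows <- stats::setNames(rep("", length(tips)), tips)
  for (cl in ape::prop.part(ape::unroot(tree))) {
    side <- tips[cl]
    if (length(side) < 2 || length(side) > length(tips) - 2) next
    col <- ifelse(tips %in% side, "A", "C")
    rows <- paste0(rows, vapply(col, function(x) strrep(x, per_edge), ""))
  }
  for (t in seq_along(tips)) {
    col <- rep("A", length(tips)); col[t] <- "G"
    rows <- paste0(rows, col)
  }
  stats::setNames(rows, tips)
}
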