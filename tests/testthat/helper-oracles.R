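# Independent oracles, written before and apart from the implementation
# they check.

# --- brute-force bigram counter over set-contexts ------------------------
# Counts (context set, successor) pairs by direct tabulation on a long
# data.frame, then normalises with the pseudocount rule.
oracle_bigram <- function(sequences, pseudocount = 0) {
  long <- do.call(rbind, lapply(sequences, function(s) {
    ctx <- character(length(s))
    seen <- character()
    for (i in seq_along(s)) {
      ctx[i] <- paste0("(", paste(sort(seen), collapse = "|"), ")")
      seen <- unique(c(seen, s[i]))
    }
    data.frame(ctx = ctx, nxt = s, stringsAsFactors = FALSE)
  }))
  out <- list()
  for (k in unique(long$ctx)) {
    sub <- long[long$ctx == k, ]
    tb <- table(sub$nxt)
    cand <- sort(names(tb))
    n <- as.numeric(tb[cand])
    out[[k]] <- stats::setNames(
      (n + pseudocount) / (sum(n) + length(cand) * pseudocount), cand)
  }
  out
}

# --- exhaustive rule-table oracle for the tea model ----------------------
# Independent flag-tuple state machine plus a flat decision table derived
# directly from the error-type definitions.  Only permitted actions are
# followed during enumeration (reachable = correct performance).
oracle_empty <- function() {
  list(filled = FALSE, boiled = FALSE, teabag_in = FALSE,
       removed = FALSE, water = FALSE, sugar = FALSE, milk = FALSE,
       stirred = FALSE, pending = FALSE)
}

oracle_apply <- function(s, a) {
  if (a == "add-water-to-kettle") s$filled <- TRUE
  if (a == "boil-water") s$boiled <- TRUE
  if (a == "add-teabag") s$teabag_in <- TRUE
  if (a == "add-boiled-water") { s$water <- TRUE; s$pending <- TRUE }
  if (a == "add-sugar") { s$sugar <- TRUE; s$pending <- TRUE }
  if (a == "add-milk") { s$milk <- TRUE; s$pending <- TRUE }
  if (a == "stir") { s$stirred <- TRUE; s$pending <- FALSE }
  if (a == "remove-teabag") { s$teabag_in <- FALSE; s$removed <- TRUE }
  s
}

# decision table: first matching row wins (non-recoverable rows first,
# then recoverable, each class in taxonomy order); "OK" if none match
oracle_classify <- function(s, a, rec) {
  rules <- list(
    list(function() a == "add-coffee", "N-OSUB"),
    list(function() a == "add-sugar" && !rec$requires_sugar, "N-ADD"),
    list(function() a == "add-milk" && !rec$requires_milk, "N-ADD"),
    list(function() a == "stir" && !rec$requires_sugar, "N-ADD"),
    list(function() a == "boil-water" && !s$filled, "N-KET"),
    list(function() a == "add-boiled-water" && !s$boiled, "N-KET"),
    list(function() a == "add-water-to-kettle" && s$filled, "R-RP"),
    list(function() a == "boil-water" && s$boiled, "R-RP"),
    list(function() a == "add-teabag" && (s$teabag_in || s$removed), "R-RP"),
    list(function() a == "add-boiled-water" && s$water, "R-RP"),
    list(function() a == "add-sugar" && s$sugar, "R-RP"),
    list(function() a == "add-milk" && s$milk, "R-RP"),
    list(function() a == "stir" && s$water && !s$pending, "R-RP"),
    list(function() a == "remove-teabag" && s$removed, "R-RP"),
    list(function() a == "remove-teabag" && !s$teabag_in && !s$removed,
         "R-SEQ"),
    list(function() a == "remove-teabag" && s$teabag_in && !s$water,
         "R-SEQ"),
    list(function() a == "stir" && !s$water, "R-SEQ")
  )
  for (r in rules) if (isTRUE(r[[1]]())) return(r[[2]])
  "OK"
}

# enumerate all oracle-states reachable by permitted actions (<= depth),
# recording, for each, one permitted path that reaches it
oracle_reachable <- function(rec, depth = 8) {
  key <- function(s) paste(vapply(s, isTRUE, logical(1)), collapse = "")
  seen <- new.env(parent = emptyenv())
  out <- list()
  queue <- list(list(s = oracle_empty(), path = character()))
  while (length(queue) > 0) {
    node <- queue[[1]]; queue <- queue[-1]
    k <- key(node$s)
    if (!is.null(seen[[k]])) next
    seen[[k]] <- TRUE
    out[[length(out) + 1]] <- node
    if (length(node$path) >= depth) next
    for (a in TEA_ACTIONS) {
      if (oracle_classify(node$s, a, rec) == "OK") {
        queue[[length(queue) + 1]] <-
          list(s = oracle_apply(node$s, a), path = c(node$path, a))
      }
    }
  }
  out
}

TEA_ACTIONS <- c("add-water-to-kettle", "boil-water", "add-teabag",
                 "add-boiled-water", "add-sugar", "add-milk", "stir",
                 "remove-teabag")

# --- matrix-algebra repeated-measures ANOVA oracle -----------------------
# Standard univariate within-subject decomposition on an orthonormalised
# contrast basis, with Mauchly's W and the Greenhouse-Geisser epsilon.
oracle_effect <- function(Y, C) {
  n <- nrow(Y); d <- ncol(C)
  Z <- Y %*% C
  zbar <- colMeans(Z)
  ss_eff <- n * sum(zbar^2)
  R <- sweep(Z, 2, zbar)
  E <- crossprod(R)
  ss_err <- sum(diag(E))
  Fval <- (ss_eff / d) / (ss_err / (d * (n - 1)))
  S <- E / (n - 1)
  eps <- sum(diag(S))^2 / (d * sum(S * S))
  mauchly_W <- NA_real_; mauchly_p <- NA_real_
  if (d >= 2) {
    mauchly_W <- det(S) / (sum(diag(S)) / d)^d
    f <- (2 * d^2 + d + 2) / (6 * d)
    chi <- -(n - 1 - f) * log(mauchly_W)
    mauchly_p <- stats::pchisq(chi, d * (d + 1) / 2 - 1, lower.tail = FALSE)
  }
  p <- stats::pf(Fval, d, d * (n - 1), lower.tail = FALSE)
  p_gg <- stats::pf(Fval, d * eps, d * (n - 1) * eps, lower.tail = FALSE)
  list(F = Fval, df1 = d, df2 = d * (n - 1), p = p, eps = eps,
       p_gg = p_gg, mauchly_W = mauchly_W, mauchly_p = mauchly_p)
}

orthonorm <- function(M) apply(M, 2, function(v) v / sqrt(sum(v^2)))

H3 <- orthonorm(matrix(c(1, -1, 0, 1, 1, -2), 3, 2))

# one-way, k = 3 levels (columns of Y)
oracle_rm_oneway <- function(Y) {
  oracle_effect(as.matrix(Y), H3)
}

# 2 x 3, columns ordered (type1:lev1..3, type2:lev1..3)
oracle_rm_2x3 <- function(Y) {
  ct <- matrix(c(1, -1) / sqrt(2), 2, 1)
  ones3 <- matrix(rep(1, 3) / sqrt(3), 3, 1)
  ones2 <- matrix(rep(1, 2) / sqrt(2), 2, 1)
  list(
    errtype = oracle_effect(as.matrix(Y), kronecker(ct, ones3)),
    contrast = oracle_effect(as.matrix(Y), kronecker(ones2, H3)),
    interaction = oracle_effect(as.matrix(Y), kronecker(ct, H3))
  )
}

# --- noncentral-t grid search for paired-t sample size -------------------
oracle_paired_n <- function(d, alpha, power) {
  for (n in 3:10000) {
    tc <- stats::qt(1 - alpha / 2, n - 1)
    pw <- 1 - stats::pt(tc, n - 1, ncp = d * sqrt(n)) +
      stats::pt(-tc, n - 1, ncp = d * sqrt(n))
    if (pw >= power) return(n)
  }
  NA_integer_
}
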