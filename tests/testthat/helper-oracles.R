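# Independent oracles used across the suite. These deliberately re-derive
# expected values by brute force / enumeration, sharing no code with the
# implementation paths they check.

# CAS check digit by direct weighted summation (weights 1,2,3,... from the
# rightmost digit of the first two segments leftward, sum mod 10).
oracle_check_digit <- function(digits) {
  d <- as.integer(strsplit(digits, "")[[1]])
  total <- 0L
  w <- 1L
  for (i in rev(seq_along(d))) {
    total <- total + d[i] * w
    w <- w + 1L
  }
  total %% 10L
}

# Quadratic pairwise scan for internal 1:1:1 conflicts within a prepared
# source-record data.frame (columns cas_clean, key, n_keys, name_norm).
oracle_internal_conflicts <- function(df) {
  n <- nrow(df)
  bad <- rep(FALSE, n)
  structured <- df$n_keys >= 1L
  bad[df$n_keys >= 2L] <- TRUE
  same <- function(a, b) !is.na(a) && !is.na(b) && a == b
  diff <- function(a, b) !is.na(a) && !is.na(b) && a != b
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (structured[i] && structured[j] &&
          df$n_keys[i] == 1L && df$n_keys[j] == 1L) {
        if (same(df$cas_clean[i], df$cas_clean[j]) &&
            diff(df$key[i], df$key[j])) bad[c(i, j)] <- TRUE
        if (same(df$key[i], df$key[j]) &&
            diff(df$cas_clean[i], df$cas_clean[j])) bad[c(i, j)] <- TRUE
      }
      if (structured[i] != structured[j] &&
          same(df$cas_clean[i], df$cas_clean[j])) bad[c(i, j)] <- TRUE
      if (!structured[i] && !structured[j]) {
        if (same(df$cas_clean[i], df$cas_clean[j]) &&
            diff(df$name_norm[i], df$name_norm[j])) bad[c(i, j)] <- TRUE
        if (same(df$name_norm[i], df$name_norm[j]) &&
            diff(df$cas_clean[i], df$cas_clean[j])) bad[c(i, j)] <- TRUE
      }
    }
  }
  bad
}

# Quadratic pairwise scan for registry uniqueness violations; one entry per
# duplicated identifier value (type:value), mirroring check_invariants.
oracle_registry_violations <- function(reg) {
  ids <- ls(reg$substances)
  subs <- lapply(ids, function(s) reg$substances[[s]])
  hits <- character()
  for (i in seq_along(subs)) {
    for (j in seq_along(subs)) {
      if (i >= j) next
      a <- subs[[i]]
      b <- subs[[j]]
      if (identical(a$cas, b$cas)) {
        hits <- c(hits, paste0("cas_collision:", a$cas))
      }
      if (identical(a$name_norm, b$name_norm)) {
        hits <- c(hits, paste0("name_collision:", a$name_norm))
      }
      if (!is.na(a$dtxcid) && identical(a$dtxcid, b$dtxcid)) {
        hits <- c(hits, paste0("structure_collision:", a$dtxcid))
      }
    }
  }
  active <- vapply(subs, `[[`, character(1), "cas")
  for (d in ls(reg$idx_deleted)) {
    if (d %in% active) hits <- c(hits, paste0("deleted_cas_is_active:", d))
  }
  sort(unique(hits))
}

# Burnside orbit count of substitution patterns: the scaffold automorphism
# group is enumerated with VF2 (igraph isomorphism search, a different
# algorithm from the BLISS generators used in the implementation), and
# counting uses the cycle-index polynomial rather than explicit orbit
# enumeration.
oracle_burnside_count <- function(scaffold, min_count = 1L,
                                  max_count = NULL, positions = NULL) {
  info <- chemregistry:::scaffold_info(scaffold)
  if (is.null(positions)) positions <- info$default_positions
  if (is.null(max_count)) max_count <- length(positions)
  n <- info$n_atoms
  nb <- nrow(info$bonds)
  edges <- integer(0)
  for (i in seq_len(nb)) {
    edges <- c(edges, info$bonds$a1[i], n + i, n + i, info$bonds$a2[i])
  }
  g <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  vcol <- c(as.integer(factor(paste(info$atoms$element, info$atoms$charge))),
            100L + as.integer(factor(info$bond_class)))
  autos <- igraph::isomorphisms(g, g, vertex.color1 = vcol,
                                vertex.color2 = vcol)
  total <- 0
  for (a in autos) {
    p <- as.integer(a)[seq_len(n)]
    perm <- match(p[positions], positions)   # action on position slots
    stopifnot(!anyNA(perm))
    # cycle lengths of perm
    seen <- rep(FALSE, length(perm))
    poly <- 1
    for (s in seq_along(perm)) {
      if (seen[s]) next
      len <- 0L
      cur <- s
      while (!seen[cur]) {
        seen[cur] <- TRUE
        cur <- perm[cur]
        len <- len + 1L
      }
      # multiply poly by (1 + x^len)
      term <- rep(0, len + 1)
      term[c(1, len + 1)] <- 1
      poly <- convolve_poly(poly, term)
    }
    ks <- seq.int(min_count, max_count) + 1L
    total <- total + sum(poly[ks[ks <= length(poly)]])
  }
  total / length(autos)
}

convolve_poly <- function(a, b) {
  out <- rep(0, length(a) + length(b) - 1L)
  for (i in seq_along(a)) {
    out[i:(i + length(b) - 1L)] <- out[i:(i + length(b) - 1L)] + a[i] * b
  }
  out
}

# Small helpers ------------------------------------------------------------

heavy_atom_counts <- function(formula) {
  # parse a Hill formula into element counts, dropping H and charge marks
  formula <- gsub("[+-]+[0-9]*$", "", formula)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  counts <- integer()
  for (p in parts) {
    el <- sub("^([A-Z][a-z]?).*$", "\\1", p)
    k <- sub("^[A-Z][a-z]?", "", p)
    k <- if (nzchar(k)) as.integer(k) else 1L
    if (el != "H") counts[el] <- (counts[el] %||% 0L) + k
  }
  counts[order(names(counts))]
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# A compact registry for resolution tests.
make_demo_registry <- function() {
  reg <- registry_new()
  s1 <- register_substance(reg, "Benzene", "71-43-2", "c1ccccc1",
                           qc = "DSSTox_High")
  s2 <- register_substance(reg, "Toluene", "108-88-3", "Cc1ccccc1")
  s3 <- register_substance(reg, "Phenol", "108-95-2", "Oc1ccccc1")
  list(reg = reg, benzene = s1, toluene = s2, phenol = s3)
}
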