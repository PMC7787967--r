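# Symmetry-aware enumeration of substitution-pattern families ("congeners")
# from a Markush-style parent: a scaffold with marked substitutable
# positions and a single-atom substituent over a range of substitution
# counts. Children are distinct up to scaffold symmetry: candidate patterns
# are reduced to orbit representatives under the scaffold's automorphism
# group, and final identity is confirmed by InChIKey so that no two returned
# children are the same molecule.

#' Describe a Markush substitution family
#'
#' @param scaffold SMILES of the parent scaffold.
#' @param substituent Element symbol of the (single-atom) substituent,
#'   e.g. `"Cl"`, `"Br"`, `"F"`, `"O"` (hydroxy), `"C"` (methyl).
#' @param positions Integer indices of substitutable scaffold atoms, in
#'   SMILES atom order. Default: every carbon with at least one free
#'   valence (an implicit hydrogen to replace).
#' @param min_count,max_count Inclusive range of substituent counts;
#'   `max_count` defaults to the number of positions.
#' @return An object of class `markush_spec`.
#' @examples
#' markush_spec("c1ccccc1-c1ccccc1", "Cl")  # polychlorinated biphenyls
#' @export
markush_spec <- function(scaffold, substituent = "Cl", positions = NULL,
                         min_count = 1L, max_count = NULL) {
  info <- scaffold_info(scaffold)
  if (is.null(positions)) {
    positions <- info$default_positions
  }
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions)) {
    stop("markush_spec: no substitutable positions", call. = FALSE)
  }
  if (any(positions < 1L | positions > info$n_atoms)) {
    stop("markush_spec: positions out of range for scaffold atoms",
         call. = FALSE)
  }
  if (any(info$free_valence[positions] < 1L)) {
    stop("markush_spec: some positions have no free valence", call. = FALSE)
  }
  if (length(positions) > 16L) {
    stop("markush_spec: at most 16 substitutable positions are supported ",
         "(exhaustive enumeration bound)", call. = FALSE)
  }
  if (!grepl("^[A-Z][a-z]?$", substituent)) {
    stop("markush_spec: substituent must be a single element symbol",
         call. = FALSE)
  }
  min_count <- as.integer(min_count)
  max_count <- if (is.null(max_count)) length(positions) else
    as.integer(max_count)
  if (min_count < 0L || max_count > length(positions) ||
      min_count > max_count) {
    stop("markush_spec: count range must lie within [0, #positions]",
         call. = FALSE)
  }
  structure(list(scaffold = scaffold, substituent = substituent,
                 positions = positions, min_count = min_count,
                 max_count = max_count, info = info),
            class = "markush_spec")
}

#' @export
print.markush_spec <- function(x, ...) {
  cat("<Markush spec>", x$scaffold, "+", x$substituent, "at",
      length(x$positions), "positions, count",
      x$min_count, "-", x$max_count, "\n")
  invisible(x)
}

# Parse a scaffold SMILES into atoms, bonds, free valences and the colored
# (vertex- and bond-class-aware) graph used for symmetry analysis. Aromatic
# bond perception comes from the MOL2 rendering so that Kekule structures of
# the same aromatic system are symmetric to each other.
scaffold_info <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  sdf_text <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, " scaffold\n")),
    error = function(e) "")
  if (!nzchar(sdf_text)) {
    stop("scaffold_info: cannot parse scaffold SMILES '", smiles, "'",
         call. = FALSE)
  }
  parsed <- parse_molblock(sdf_text)
  atoms <- parsed$atoms
  bonds <- parsed$bonds

  # aromatic bond classes from the MOL2 rendering of the same input
  mol2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", paste0(smiles, " scaffold\n")),
    error = function(e) "")
  ar <- mol2_aromatic_bonds(mol2)
  bond_class <- as.character(bonds$order)
  if (!is.null(ar) && nrow(ar)) {
    k1 <- paste(pmin(bonds$a1, bonds$a2), pmax(bonds$a1, bonds$a2))
    k2 <- paste(pmin(ar$a1, ar$a2), pmax(ar$a1, ar$a2))
    bond_class[k1 %in% k2] <- "ar"
  }

  std_val <- c(C = 4, N = 3, O = 2, S = 2, P = 3, B = 3,
               F = 1, Cl = 1, Br = 1, I = 1, H = 1)
  order_sum <- vapply(seq_len(nrow(atoms)), function(i) {
    sel <- bonds$a1 == i | bonds$a2 == i
    sum(bonds$order[sel])
  }, numeric(1L))
  free <- unname(std_val[atoms$element]) - order_sum + atoms$hcount
  free[is.na(free)] <- 0

  list(smiles = smiles,
       n_atoms = nrow(atoms),
       atoms = atoms, bonds = bonds, bond_class = bond_class,
       free_valence = as.integer(pmax(free, 0)),
       default_positions =
         which(atoms$element == "C" & free >= 1 & atoms$charge == 0))
}

# Minimal V2000 counts/atom/bond extraction (via ChemmineR's SDF reader).
parse_molblock <- function(sdf_text) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(sdf_text, tmp)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(tmp))
  sdf <- sdfset[[1L]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  element <- sub("_[0-9]+$", "", rownames(ab))
  atoms <- data.frame(element = element,
                      x = ab[, 1L], y = ab[, 2L],
                      z = if (ncol(ab) >= 3L) ab[, 3L] else 0,
                      charge = if ("charge" %in% colnames(ab))
                        ab[, "charge"] else 0,
                      hcount = 0L,
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  bonds <- data.frame(a1 = as.integer(bb[, 1L]),
                      a2 = as.integer(bb[, 2L]),
                      order = as.integer(bb[, 3L]))
  list(atoms = atoms, bonds = bonds)
}

mol2_aromatic_bonds <- function(mol2_text) {
  if (!nzchar(mol2_text)) return(NULL)
  lines <- strsplit(mol2_text, "\n", fixed = TRUE)[[1L]]
  start <- which(lines == "@<TRIPOS>BOND")
  if (!length(start)) return(NULL)
  end <- c(grep("^@<TRIPOS>", lines), length(lines) + 1L)
  end <- min(end[end > start[1L]])
  block <- lines[(start[1L] + 1L):(end - 1L)]
  block <- block[nzchar(trimws(block))]
  if (!length(block)) return(NULL)
  f <- do.call(rbind, lapply(strsplit(trimws(block), "[[:space:]]+"),
                             function(x) x[1:4]))
  ar <- f[f[, 4L] == "ar", , drop = FALSE]
  data.frame(a1 = as.integer(ar[, 2L]), a2 = as.integer(ar[, 3L]))
}

# Automorphism group of the scaffold acting on atom indices, respecting
# element, formal charge and bond class (single/double/triple/aromatic).
# Bond classes are encoded by subdividing each bond with a colored vertex.
scaffold_automorphisms <- function(info) {
  n <- info$n_atoms
  nb <- nrow(info$bonds)
  edges <- integer(0)
  for (i in seq_len(nb)) {
    edges <- c(edges, info$bonds$a1[i], n + i, n + i, info$bonds$a2[i])
  }
  g <- igraph::make_graph(edges = edges, n = n + nb, directed = FALSE)
  vcol <- c(as.integer(factor(paste(info$atoms$element, info$atoms$charge))),
            100L + as.integer(factor(info$bond_class)))
  gens <- igraph::automorphism_group(g, colors = vcol)
  gens <- lapply(gens, function(p) as.integer(p)[seq_len(n)])
  permutation_closure(gens, n)
}

# Close a set of permutation generators under composition (groups here are
# small; hard cap guards against pathological input).
permutation_closure <- function(gens, n, cap = 100000L) {
  idp <- seq_len(n)
  seen <- new.env(parent = emptyenv())
  keyf <- function(p) paste(p, collapse = ",")
  group <- list(idp)
  seen[[keyf(idp)]] <- TRUE
  queue <- list(idp)
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    for (g in gens) {
      nxt <- cur[g]
      k <- keyf(nxt)
      if (is.null(seen[[k]])) {
        seen[[k]] <- TRUE
        group[[length(group) + 1L]] <- nxt
        queue[[length(queue) + 1L]] <- nxt
        if (length(group) > cap) {
          stop("permutation_closure: group larger than cap", call. = FALSE)
        }
      }
    }
  }
  group
}

#' Enumerate the children of a Markush substitution family
#'
#' Generates every distinct child structure obtained by placing the
#' substituent on `min_count` to `max_count` of the marked positions.
#' Substitution patterns are first reduced to orbit representatives under
#' the scaffold's automorphism group (so symmetric placements are counted
#' once), then rendered as molfiles and deduplicated by InChIKey, which is
#' the registry's structure identity.
#'
#' @param spec A [markush_spec()].
#' @return A data.frame with one row per distinct child: `key` (InChIKey),
#'   `smiles` (canonical), `n_subst`, and `positions` (slash-separated
#'   position indices of the representative pattern). The attribute
#'   `"parent"` carries the scaffold SMILES.
#' @examples
#' pcb <- markush_spec("c1ccccc1-c1ccccc1", "Cl")
#' nrow(enumerate_markush(pcb))  # the 209 polychlorinated biphenyls
#' @export
enumerate_markush <- function(spec) {
  stopifnot(inherits(spec, "markush_spec"))
  info <- spec$info
  pos <- spec$positions
  group <- scaffold_automorphisms(info)
  # restrict group action to the substitutable positions
  pos_index <- match(seq_len(info$n_atoms), pos)  # atom -> position slot
  gpos <- lapply(group, function(p) {
    img <- pos_index[p[pos]]
    if (anyNA(img)) NULL else img
  })
  gpos <- unique(Filter(Negate(is.null), gpos))

  reps <- list()
  for (k in seq.int(spec$min_count, spec$max_count)) {
    if (k == 0L) {
      reps[[length(reps) + 1L]] <- integer(0)
      next
    }
    subsets <- utils::combn(length(pos), k, simplify = FALSE)
    canon_seen <- new.env(parent = emptyenv())
    for (s in subsets) {
      canon <- canonical_subset(s, gpos)
      ck <- paste(canon, collapse = ",")
      if (is.null(canon_seen[[ck]])) {
        canon_seen[[ck]] <- TRUE
        reps[[length(reps) + 1L]] <- s
      }
    }
  }

  mols <- vapply(reps, function(s)
    child_molblock(info, pos[s], spec$substituent), character(1L))
  keys <- molblock_keys(mols)
  smiles <- molblock_smiles(mols)
  out <- data.frame(key = keys, smiles = smiles,
                    n_subst = vapply(reps, length, integer(1L)),
                    positions = vapply(reps, function(s)
                      paste(pos[s], collapse = "/"), character(1L)),
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$key) & !duplicated(out$key), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "parent") <- spec$scaffold
  out
}

canonical_subset <- function(s, gpos) {
  best <- sort(s)
  bk <- paste(best, collapse = ",")
  for (g in gpos) {
    img <- sort(g[s])
    ik <- paste(img, collapse = ",")
    if (ik < bk) {
      best <- img
      bk <- ik
    }
  }
  best
}

# Render a child as a V2000 molfile: scaffold atoms/bonds plus one
# substituent atom singly bonded to each chosen position. Coordinates are
# irrelevant to InChI; substituents get a small offset for readability.
child_molblock <- function(info, atom_positions, substituent) {
  a <- info$atoms
  b <- info$bonds
  na <- nrow(a) + length(atom_positions)
  nb <- nrow(b) + length(atom_positions)
  lines <- c("child", "  chemregistry", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atom_line <- function(x, y, z, el)
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            x, y, z, el)
  for (i in seq_len(nrow(a))) {
    lines <- c(lines, atom_line(a$x[i], a$y[i], a$z[i], a$element[i]))
  }
  for (j in seq_along(atom_positions)) {
    p <- atom_positions[j]
    lines <- c(lines, atom_line(a$x[p] + 0.45, a$y[p] + 0.45, a$z[p],
                                substituent))
  }
  bond_line <- function(a1, a2, o) sprintf("%3d%3d%3d  0  0  0  0", a1, a2, o)
  for (i in seq_len(nrow(b))) {
    lines <- c(lines, bond_line(b$a1[i], b$a2[i], b$order[i]))
  }
  for (j in seq_along(atom_positions)) {
    lines <- c(lines, bond_line(atom_positions[j], nrow(a) + j, 1L))
  }
  paste(c(lines, "M  END", "$$$$"), collapse = "\n")
}

molblock_keys <- function(molblocks) {
  if (!length(molblocks)) return(character())
  res <- convert_one("SDF", "INCHIKEY",
                     paste0(paste(molblocks, collapse = "\n"), "\n"))
  res <- trimws(res)
  res <- res[nzchar(res)]
  if (length(res) == length(molblocks) && all(grepl(inchikey_regex, res))) {
    return(res)
  }
  vapply(molblocks, function(m) {
    l <- trimws(convert_one("SDF", "INCHIKEY", paste0(m, "\n")))
    l <- l[nzchar(l)]
    if (length(l) == 1L && grepl(inchikey_regex, l)) l else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

molblock_smiles <- function(molblocks) {
  if (!length(molblocks)) return(character())
  res <- convert_one("SDF", "CAN",
                     paste0(paste(molblocks, collapse = "\n"), "\n"))
  res <- trimws(sub("\t.*$", "", res))
  res <- res[nzchar(res)]
  if (length(res) == length(molblocks)) return(res)
  rep(NA_character_, length(molblocks))
}

#' Count Markush children without materializing structures
#'
#' Convenience wrapper returning `nrow(enumerate_markush(spec))`.
#'
#' @param spec A [markush_spec()].
#' @return Integer count of distinct children.
#' @export
markush_child_count <- function(spec) {
  nrow(enumerate_markush(spec))
}
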