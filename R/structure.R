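# Structure canonicalization and keying, plus derivation of the QSAR-ready
# and MS-ready forms used for modeling and mass-spectrometry matching.
#
# Molecules are carried as SMILES strings at the module surface; SDF/molfile
# input is converted on ingestion (see read_sdf). Identity is the standard
# InChIKey computed through Open Babel (ChemmineOB).

.chemreg_cache <- new.env(parent = emptyenv())

ob_quiet <- function(expr) {
  # Open Babel writes parse warnings to the C-level stderr; they are not
  # catchable conditions, so per-record failures are detected from output
  # shape instead (NA keys), and we leave the stream alone.
  expr
}

inchikey_regex <- "^[A-Z]{14}-[A-Z]{10}-[A-Z]$"

no_ops <- function() data.frame(names = character(), args = character())

convert_one <- function(from, to, input, options = no_ops()) {
  out <- tryCatch(
    ChemmineOB::convertFormat(from, to, source = input, options = options),
    error = function(e) "")
  strsplit(out, "\n", fixed = TRUE)[[1L]]
}

#' Compute structure identity keys (standard InChIKey)
#'
#' The registry's structure identity is the standard InChIKey: a fixed-length
#' hash of the canonical InChI, invariant under atom reordering and 2D
#' coordinate changes, and distinct for stereo-distinct inputs. Keys are
#' memoized per session.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of InChIKeys; `NA` where a string cannot be
#'   parsed as a structure.
#' @examples
#' structure_key("c1ccccc1")
#' structure_key(c("C/C=C/C", "C/C=C\\C"))  # E and Z give distinct keys
#' @export
structure_key <- function(smiles) {
  smiles <- as.character(smiles)
  out <- rep(NA_character_, length(smiles))
  if (!length(smiles)) return(out)
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (!any(ok)) return(out)

  cache <- get_key_cache()
  todo <- unique(smiles[ok])
  todo <- todo[!vapply(todo, function(s) !is.null(cache[[s]]), logical(1L))]
  if (length(todo)) {
    keys <- keys_via_ob(todo)
    for (i in seq_along(todo)) cache[[todo[i]]] <- keys[i]
  }
  out[ok] <- vapply(smiles[ok], function(s) cache[[s]], character(1L),
                    USE.NAMES = FALSE)
  out
}

get_key_cache <- function() {
  if (is.null(.chemreg_cache$keys)) {
    .chemreg_cache$keys <- new.env(parent = emptyenv())
  }
  .chemreg_cache$keys
}

keys_via_ob <- function(smiles) {
  # One batch call when everything parses; Open Babel stops emitting at the
  # first bad record, so a short result triggers a per-molecule fallback.
  src <- paste0(paste(smiles, seq_along(smiles)), collapse = "\n")
  lines <- convert_one("SMI", "INCHIKEY", paste0(src, "\n"))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == length(smiles) && all(grepl(inchikey_regex, lines))) {
    return(lines)
  }
  vapply(smiles, function(s) {
    l <- trimws(convert_one("SMI", "INCHIKEY", paste0(s, "\n")))
    l <- l[nzchar(l)]
    if (length(l) == 1L && grepl(inchikey_regex, l)) l else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Canonical SMILES via Open Babel
#'
#' @param smiles Character vector of SMILES.
#' @return Canonical SMILES strings (`NA` for unparseable input).
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_character_)
    l <- convert_one("SMI", "CAN", paste0(s, "\n"))
    l <- trimws(sub("\t.*$", "", l))
    l <- l[nzchar(l)]
    if (length(l) == 1L) l else NA_character_
  }, character(1L), USE.NAMES = FALSE)
}

#' Molecular formula and masses for a structure
#'
#' @param smiles A single SMILES string.
#' @return List with `formula` (Hill notation), `average_mass` and
#'   `monoisotopic_mass` in Daltons, or `NULL` if unparseable.
#' @export
mol_properties <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  res <- tryCatch({
    mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity)
    p <- ChemmineOB::prop_OB(mols)
    m <- ChemmineOB::exactMass_OB(mols)
    list(formula = p$formula[1L], average_mass = p$MW[1L],
         monoisotopic_mass = m[[1L]])
  }, error = function(e) NULL)
  res
}

#' Split a SMILES into covalently disconnected components
#'
#' @param smiles A single SMILES string (components separated by `.`).
#' @return Character vector of component SMILES.
#' @export
split_components <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  strsplit(as.character(smiles), ".", fixed = TRUE)[[1L]]
}

has_carbon <- function(component_smiles) {
  # An organic component contains at least one carbon atom. Match C/c as an
  # element symbol: reject when the only C's belong to Cl/Ca/Cd/Co/Cr/Cu/Cs/Ce.
  grepl("C(?![lardouse])|c", component_smiles, perl = TRUE)
}

#' Default counterion/fragment dictionary for desalting
#'
#' Canonical SMILES of components removed during desalting when at least one
#' non-dictionary organic component remains: alkali and alkaline-earth
#' cations, halides, water and other common counterions, plus a few frequent
#' small organic counterions (acetate, formate, oxalate, mesylate, tosylate).
#' The list is deliberately small and meant to be extended via the
#' `extra` argument of [qsar_ready()] / [ms_ready()].
#'
#' @return Character vector of canonical SMILES.
#' @export
default_salt_dictionary <- function() {
  raw <- c(
    "[Li+]", "[Na+]", "[K+]", "[Rb+]", "[Cs+]",
    "[Mg+2]", "[Ca+2]", "[Sr+2]", "[Ba+2]", "[Zn+2]", "[Al+3]",
    "[F-]", "[Cl-]", "[Br-]", "[I-]",
    "F", "Cl", "Br", "I",
    "O", "[OH-]", "N", "[NH4+]",
    "O=S(=O)(O)O", "[O-]S(=O)(=O)[O-]", "O=[N+]([O-])O", "[O-][N+]([O-])=O",
    "OP(=O)(O)O", "O=C=O",
    # small organic counterions
    "CC(=O)O", "CC(=O)[O-]", "OC=O", "[O-]C=O",
    "OC(=O)C(=O)O", "CS(=O)(=O)O", "Cc1ccc(cc1)S(=O)(=O)O"
  )
  unique(stats::na.omit(canonical_smiles(raw)))
}

strip_stereo_isotopes <- function(smiles) {
  # Remove chirality marks (@), directional bonds (/ \) and isotope labels
  # ([13C] -> [C], [2H] -> [H]); bracket hydrogen counts written for
  # stereocenters remain valid SMILES after the marks are dropped.
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("[/\\\\]", "", s)
  gsub("\\[([0-9]+)", "[", s)
}

neutralize_smiles <- function(smiles) {
  out <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(smiles, "\n"),
      options = data.frame(names = "neutralize", args = "")),
    error = function(e) "")
  out <- trimws(sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1L]]))
  out <- out[nzchar(out)]
  if (length(out) == 1L) out else smiles
}

# Shared desalting core. Returns list(components, excluded, reason) where
# components are stereo/isotope-stripped, neutralized canonical SMILES of the
# surviving organic components (possibly several, for ms_ready to dedupe).
desalt_components <- function(smiles, extra = character()) {
  comps <- split_components(smiles)
  comps <- comps[nzchar(comps)]
  if (!length(comps)) {
    return(list(components = character(), excluded = TRUE,
                reason = "empty structure"))
  }
  dict <- c(default_salt_dictionary(), stats::na.omit(canonical_smiles(extra)))
  can <- canonical_smiles(comps)
  if (anyNA(can)) {
    stop("qsar/ms processing: unparseable component in '", smiles, "'",
         call. = FALSE)
  }
  organic <- has_carbon(can)
  in_dict <- can %in% dict
  keep <- organic & !in_dict
  dict_fallback <- FALSE
  if (!any(keep)) {
    # nothing but counterions/inorganics: the organic dictionary components
    # themselves (e.g. acetate in sodium acetate) are the survivors
    keep <- organic
    dict_fallback <- TRUE
  }
  if (!any(keep)) {
    return(list(components = character(), excluded = TRUE,
                reason = "no organic component"))
  }
  surv <- unique(can[keep])
  surv <- vapply(surv, function(s) {
    s2 <- neutralize_smiles(s)
    cs <- canonical_smiles(strip_stereo_isotopes(s2))
    if (is.na(cs)) s2 else cs
  }, character(1L), USE.NAMES = FALSE)
  list(components = unique(surv), excluded = FALSE, reason = NA_character_,
       dict_fallback = dict_fallback)
}

pick_largest <- function(components) {
  # survivor = largest component by average mass; ties broken by higher
  # monoisotopic mass, then lexicographic structure key (deterministic)
  if (length(components) == 1L) return(components)
  props <- lapply(components, mol_properties)
  mw <- vapply(props, function(p) if (is.null(p)) -Inf else p$average_mass,
               numeric(1L))
  mim <- vapply(props, function(p) if (is.null(p)) -Inf else
    p$monoisotopic_mass, numeric(1L))
  key <- structure_key(components)
  ord <- order(-mw, -mim, key)
  components[ord[1L]]
}

#' Derive the QSAR-ready form of a structure
#'
#' QSAR-ready structures are desalted to a single organic component with all
#' stereochemistry descriptors and isotope labels removed and charges
#' neutralized. Records that desalting cannot reduce to exactly one organic
#' component (true multicomponent substances, e.g. a salt of two active
#' organics, or purely inorganic records) are excluded rather than guessed
#' at.
#'
#' @param smiles A single SMILES string.
#' @param extra Additional counterion SMILES to treat as removable salt
#'   components, beyond [default_salt_dictionary()].
#' @return A list of class `qsar_form`: `smiles` (canonical, `NA` when
#'   excluded), `key` (InChIKey), `excluded` (logical), `reason`.
#' @examples
#' qsar_ready("CC(=O)[O-].[Na+]")$smiles   # acetic acid survives desalting
#' @export
qsar_ready <- function(smiles, extra = character()) {
  d <- desalt_components(smiles, extra)
  if (d$excluded) {
    return(structure(list(smiles = NA_character_, key = NA_character_,
                          excluded = TRUE, reason = d$reason),
                     class = "qsar_form"))
  }
  keys <- structure_key(d$components)
  distinct <- !duplicated(keys)
  comps <- d$components[distinct]
  if (length(comps) > 1L) {
    if (!isTRUE(d$dict_fallback)) {
      return(structure(list(smiles = NA_character_, key = NA_character_,
                            excluded = TRUE,
                            reason = "multiple distinct organic components"),
                       class = "qsar_form"))
    }
    # all survivors are themselves dictionary counterions; the largest is
    # the desalting survivor
    comps <- pick_largest(comps)
  }
  structure(list(smiles = comps[1L], key = structure_key(comps[1L]),
                 excluded = FALSE, reason = NA_character_),
            class = "qsar_form")
}

#' @export
print.qsar_form <- function(x, ...) {
  if (x$excluded) cat("<QSAR-ready: excluded>", x$reason, "\n")
  else cat("<QSAR-ready>", x$smiles, " key:", x$key, "\n")
  invisible(x)
}

#' Derive the MS-ready form(s) of a structure
#'
#' MS-ready processing desalts and strips stereochemistry and isotopes like
#' [qsar_ready()], but mixtures are retained: every distinct surviving
#' organic component is kept, with duplicate components (equal InChIKey,
#' e.g. two equivalents of the same ion) collapsed to one. Components are
#' returned in canonical order by key.
#'
#' @inheritParams qsar_ready
#' @return A list of class `ms_form`: `smiles` (character vector), `keys`
#'   (matching InChIKeys), `excluded`, `reason`.
#' @export
ms_ready <- function(smiles, extra = character()) {
  d <- desalt_components(smiles, extra)
  if (d$excluded) {
    return(structure(list(smiles = character(), keys = character(),
                          excluded = TRUE, reason = d$reason),
                     class = "ms_form"))
  }
  keys <- structure_key(d$components)
  dup <- duplicated(keys)
  comps <- d$components[!dup]
  keys <- keys[!dup]
  ord <- order(keys)
  structure(list(smiles = comps[ord], keys = keys[ord],
                 excluded = FALSE, reason = NA_character_),
            class = "ms_form")
}

#' @export
print.ms_form <- function(x, ...) {
  if (x$excluded) cat("<MS-ready: excluded>", x$reason, "\n")
  else cat("<MS-ready>", length(x$smiles), "component(s):",
           paste(x$smiles, collapse = " | "), "\n")
  invisible(x)
}
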