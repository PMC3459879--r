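# Coarse-grained (C-alpha) structure handling.
#
# A coarse_model is the single-structure unit of the whole pipeline: one
# C-alpha record per residue, with chain / residue-number / insertion-code
# bookkeeping and the experimental isotropic B-factor carried along.

# modified amino acids whose backbone is deposited as HETATM in many entries
.modified_aa <- c("MSE", "SEC", "PYL", "MLY", "CSO", "PTR", "SEP", "TPO",
                  "HYP", "KCX", "CME", "MLE", "M3L", "CSD", "OCS")

#' Construct a coarse C-alpha model
#'
#' @param id text label for the structure (e.g. PDB code plus model index).
#' @param chain character vector of per-residue chain identifiers.
#' @param resno integer vector of author-assigned residue numbers.
#' @param xyz numeric N x 3 matrix of C-alpha coordinates in Angstrom.
#' @param bfactor per-residue isotropic B-factors (Angstrom^2); recycled if
#'   length 1.
#' @param insert optional per-residue insertion codes ("" when absent).
#'
#' @return An object of class `coarse_model`: a list with elements `id`,
#'   `chain`, `resno`, `insert`, `xyz`, `bfactor` and residue count `N`.
#' @export
coarse_model <- function(id, chain, resno, xyz, bfactor = 0, insert = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop_lm("coordinates must be an N x 3 matrix", "shape_error")
  n <- nrow(xyz)
  if (is.null(insert)) insert <- rep("", n)
  insert[is.na(insert)] <- ""
  chain <- as.character(chain)
  resno <- as.integer(resno)
  bfactor <- rep_len(as.numeric(bfactor), n)
  if (length(chain) != n || length(resno) != n || length(insert) != n)
    stop_lm("chain, resno, insert and coordinates must agree in length", "shape_error")
  if (any(!is.finite(xyz)))
    stop_lm("non-finite coordinates", "format_error")
  keys <- residue_keys(chain, resno, insert)
  if (anyDuplicated(keys))
    stop_lm(sprintf("duplicate residue identifiers: %s",
                    paste(unique(keys[duplicated(keys)]), collapse = ", ")),
            "format_error")
  structure(list(id = as.character(id), chain = chain, resno = resno,
                 insert = insert, xyz = unname(xyz), bfactor = bfactor, N = n),
            class = "coarse_model")
}

#' @export
print.coarse_model <- function(x, ...) {
  cat(sprintf("coarse_model '%s': %d residues, chains %s\n",
              x$id, x$N, paste(unique(x$chain), collapse = ",")))
  invisible(x)
}

model_keys <- function(model) residue_keys(model$chain, model$resno, model$insert)

#' Load a C-alpha model from a PDB file
#'
#' Reads a PDB-format file and extracts one C-alpha record per residue.
#' Alternate locations are resolved by keeping the highest-occupancy record
#' (ties broken by alphabetical altloc label); residues without a C-alpha are
#' skipped with a warning. HETATM C-alpha records are accepted only for common
#' modified amino acids, so ligands, ions and waters are never included.
#'
#' @param source path to a PDB-format file.
#' @param model_index which MODEL of a multi-model file to use (default 1).
#' @param chain_filter optional character vector restricting the chains kept.
#' @param id label for the returned model; defaults to the file base name.
#'
#' @return A [coarse_model()].
#' @export
load_structure <- function(source, model_index = 1L, chain_filter = NULL,
                           id = NULL) {
  if (!file.exists(source)) stop_lm(sprintf("cannot read '%s'", source), "io_error")
  pdb <- tryCatch(
    bio3d::read.pdb(source, multi = model_index > 1L, rm.alt = FALSE,
                    verbose = FALSE),
    error = function(e) stop_lm(sprintf("failed to parse '%s': %s",
                                        source, conditionMessage(e)), "io_error"))
  at <- pdb$atom
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  is_ca <- at$elety == "CA" &
    (at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% .modified_aa))
  protein <- at$type == "ATOM" | (at$type == "HETATM" & at$resid %in% .modified_aa)

  if (!is.null(chain_filter)) {
    is_ca <- is_ca & at$chain %in% chain_filter
    protein <- protein & at$chain %in% chain_filter
  }
  ca <- at[is_ca, , drop = FALSE]
  if (nrow(ca) == 0L)
    stop_lm("no C-alpha atoms after filtering", "empty_model_error")

  # residues present in the polymer but lacking a C-alpha record
  all_res <- unique(residue_keys(at$chain[protein], at$resno[protein],
                                 at$insert[protein]))
  ca_res <- unique(residue_keys(ca$chain, ca$resno, ca$insert))
  missing_ca <- setdiff(all_res, ca_res)
  if (length(missing_ca))
    warning(sprintf("%s: %d residue(s) lack a C-alpha and were skipped",
                    basename(source), length(missing_ca)), call. = FALSE)

  # altloc resolution: highest occupancy, ties by altloc label order
  key <- residue_keys(ca$chain, ca$resno, ca$insert)
  ord <- order(key, -ca$o, ca$alt)
  ca <- ca[ord, , drop = FALSE]
  key <- key[ord]
  dup <- duplicated(key)
  bare_dup <- key[dup][ca$alt[dup] == "" ]
  if (length(bare_dup))
    stop_lm(sprintf("duplicate C-alpha without altloc for residue(s): %s",
                    paste(unique(bare_dup), collapse = ", ")), "format_error")
  ca <- ca[!dup, , drop = FALSE]
  # restore file order of residues
  ca <- ca[order(as.integer(rownames(ca))), , drop = FALSE]

  coords <- as.matrix(ca[, c("x", "y", "z")])
  if (model_index > 1L) {
    nmod <- nrow(pdb$xyz)
    if (is.null(nmod) || nmod < model_index)
      stop_lm(sprintf("model %d not present in '%s'", model_index, source),
              "io_error")
    sel_xyz <- atom2xyz_rows(as.integer(rownames(ca)))
    coords <- matrix(pdb$xyz[model_index, sel_xyz], ncol = 3L, byrow = TRUE)
  }

  if (is.null(id)) {
    id <- paste0(sub("\\.(pdb|ent)(\\.gz)?$", "", basename(source)),
                 if (model_index > 1L) paste0("_m", model_index) else "")
  }
  coarse_model(id = id, chain = ca$chain, resno = ca$resno, insert = ca$insert,
               xyz = coords, bfactor = ca$b)
}

atom2xyz_rows <- function(atom_rows) {
  as.vector(rbind(3L * atom_rows - 2L, 3L * atom_rows - 1L, 3L * atom_rows))
}

#' Per-residue experimental B-factors
#'
#' @param model a [coarse_model()].
#' @param chains optional character vector of chains to select (default: all).
#'
#' @return Numeric vector of B-factors (Angstrom^2) in residue order.
#' @export
experimental_bfactors <- function(model, chains = NULL) {
  if (is.null(chains)) return(model$bfactor)
  missing <- setdiff(chains, unique(model$chain))
  if (length(missing))
    stop_lm(sprintf("chain(s) not present: %s", paste(missing, collapse = ", ")),
            "selection_error")
  model$bfactor[model$chain %in% chains]
}

#' Write a coarse model as a PDB-format file
#'
#' One ATOM record (C-alpha) per residue; coordinates at the format's
#' 3-decimal precision.
#'
#' @param model a [coarse_model()].
#' @param file output path.
#' @return Invisibly, `file`.
#' @export
write_structure <- function(model, file) {
  bio3d::write.pdb(file = file,
                   xyz = xyz_to_vec(model$xyz),
                   type = rep("ATOM", model$N),
                   resno = model$resno,
                   resid = rep("ALA", model$N),
                   eleno = seq_len(model$N),
                   elety = rep("CA", model$N),
                   chain = model$chain,
                   insert = ifelse(model$insert == "", NA, model$insert),
                   b = model$bfactor,
                   o = rep(1, model$N))
  invisible(file)
}

#' Fetch PDB entries into a local cache
#'
#' Downloads each 4-character accession from the RCSB archive unless a cached
#' copy already exists. All analysis functions accept plain local paths, so
#' this helper is only a convenience for assembling datasets.
#'
#' @param accessions character vector of 4-character PDB identifiers.
#' @param cache_dir directory for cached files (created if needed).
#' @return Named character vector of local file paths.
#' @export
fetch_structures <- function(accessions,
                             cache_dir = file.path(tools::R_user_dir("loopmodes", "cache"), "pdb")) {
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  out <- character(length(accessions))
  names(out) <- accessions
  for (acc in accessions) {
    if (!grepl("^[0-9][A-Za-z0-9]{3}$", acc))
      stop_lm(sprintf("'%s' is not a valid PDB accession", acc), "usage_error")
    dest <- file.path(cache_dir, paste0(tolower(acc), ".pdb"))
    if (!file.exists(dest)) {
      url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(acc))
      ok <- tryCatch(utils::download.file(url, dest, quiet = TRUE) == 0,
                     error = function(e) FALSE, warning = function(w) FALSE)
      if (!ok || !file.exists(dest)) {
        unlink(dest)
        stop_lm(sprintf("structure %s not available locally (%s) and could not be fetched",
                        acc, dest), "io_error")
      }
    }
    out[[acc]] <- dest
  }
  out
}
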