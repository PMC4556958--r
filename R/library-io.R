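# Labeled compound library I/O.
#
# A library is a tibble with one row per molecule:
#   mol_id      character, unique
#   label       "active" / "inactive" / "unknown"
#   mol_weight  daltons
#   structure   list of parsed molecular graphs (NULL for feature clouds)
#   sdf         list of ChemmineR SDF objects    (NULL for feature clouds)
#   conformers  list of tibbles (conf_id, atom, x, y, z)
#   features    list of tibbles (conf_id, ftype, x, y, z, ...)

new_library <- function(mol_id, label, mol_weight = NA_real_,
                        structure = NULL, sdf = NULL,
                        conformers = NULL, features = NULL) {
  nmol <- length(mol_id)
  lib <- tibble(
    mol_id = as.character(mol_id),
    label = as.character(label),
    mol_weight = rep_len(mol_weight, nmol),
    structure = structure %||% rep(list(NULL), nmol),
    sdf = sdf %||% rep(list(NULL), nmol),
    conformers = conformers %||% rep(list(NULL), nmol),
    features = features %||% rep(list(NULL), nmol)
  )
  check_labels(lib$label)
  assert_library(lib)
  lib
}

read_smiles_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  tibble(
    smiles = map_chr(parts, 1),
    mol_id = imap_chr_default(parts)
  )
}

sdfset_from_list <- function(sdf_list, ids) {
  methods::new("SDFset", SDF = unname(sdf_list), ID = as.character(ids))
}

# Molecular weights via OpenBabel (implicit hydrogens included).
map2_dbl_safe <- function(sdf_list, ids) {
  if (length(sdf_list) == 0) return(numeric(0))
  out <- tryCatch(
    suppressWarnings(ChemmineR::propOB(sdfset_from_list(sdf_list, ids))$MW),
    error = function(e) NULL
  )
  if (is.null(out) || length(out) != length(sdf_list)) {
    out <- rep(NA_real_, length(sdf_list))
  }
  as.numeric(out)
}

imap_chr_default <- function(parts) {
  map_chr(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else paste0("mol", i)
  })
}

#' Read a labeled compound library
#'
#' Reads structures from a SMILES file (one record per line, optional
#' title) or an SDF (V2000) file, joins activity labels from a CSV with
#' columns `mol_id,label`, and parses each structure into the internal
#' molecular graph. Structures that fail to parse are dropped with a
#' warning (their ids are kept in the `"failures"` attribute); molecules
#' without a label get `"unknown"`.
#'
#' @param structure_path Path to a `.smi`/`.smiles` or `.sdf` file.
#' @param label_path Path to a CSV with columns `mol_id`, `label`
#'   (values `active`/`inactive`), or `NULL` for an unlabeled library.
#' @return A molecule library tibble (see [generate_conformers()],
#'   [perceive_features()] for the downstream steps).
#' @examples
#' \donttest{
#' lib <- make_smiles_fixture()
#' dplyr::count(lib, label)
#' }
#' @export
read_labeled_library <- function(structure_path, label_path = NULL) {
  if (!file.exists(structure_path)) {
    abort(paste0("structure file not found: ", structure_path))
  }
  labels <- NULL
  if (!is.null(label_path)) {
    if (!file.exists(label_path)) {
      abort(paste0("label file not found: ", label_path))
    }
    labels <- readr::read_csv(label_path, show_col_types = FALSE,
                              progress = FALSE)
    if (!all(c("mol_id", "label") %in% names(labels))) {
      abort("label file must have columns mol_id, label")
    }
    labels$mol_id <- as.character(labels$mol_id)
    check_labels(labels$label)
    if (anyDuplicated(labels$mol_id)) {
      dup <- unique(labels$mol_id[duplicated(labels$mol_id)])
      abort(paste0("duplicate mol_id in label file: ",
                   paste(dup, collapse = ", ")))
    }
  }

  ext <- tolower(tools::file_ext(structure_path))
  failures <- character()
  if (ext %in% c("smi", "smiles", "txt", "ism")) {
    rec <- read_smiles_lines(structure_path)
    if (anyDuplicated(rec$mol_id)) {
      dup <- unique(rec$mol_id[duplicated(rec$mol_id)])
      abort(paste0("duplicate mol_id in structure file: ",
                   paste(dup, collapse = ", ")))
    }
    sdf_list <- map(seq_len(nrow(rec)), function(i) {
      smi <- setNames(rec$smiles[i], rec$mol_id[i])
      res <- tryCatch(
        suppressWarnings(ChemmineR::smiles2sdf(smi)),
        error = function(e) NULL
      )
      if (is.null(res) || length(res) < 1) return(NULL)
      sdf <- res[[1]]
      if (nrow(ChemmineR::atomblock(sdf)) == 0) return(NULL)
      sdf
    })
    parsed <- !map_lgl(sdf_list, is.null)
    failures <- rec$mol_id[!parsed]
    rec <- rec[parsed, ]
    sdf_list <- sdf_list[parsed]
    mol_ids <- rec$mol_id
  } else {
    sdfset <- ChemmineR::read.SDFset(structure_path)
    ok <- ChemmineR::validSDF(sdfset)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids)] <- paste0("mol", which(!nzchar(ids)))
    failures <- ids[!ok]
    sdfset <- sdfset[ok]
    mol_ids <- ids[ok]
    if (anyDuplicated(mol_ids)) {
      dup <- unique(mol_ids[duplicated(mol_ids)])
      abort(paste0("duplicate mol_id in structure file: ",
                   paste(dup, collapse = ", ")))
    }
    sdf_list <- map(seq_along(sdfset), function(i) sdfset[[i]])
  }
  if (length(failures) > 0) {
    warn(paste0(length(failures), " structure(s) failed to parse: ",
                paste(failures, collapse = ", ")))
  }

  graphs <- map(sdf_list, parse_molgraph)
  mw <- map2_dbl_safe(sdf_list, mol_ids)

  lab <- rep("unknown", length(mol_ids))
  if (!is.null(labels)) {
    m <- match(mol_ids, labels$mol_id)
    lab[!is.na(m)] <- labels$label[m[!is.na(m)]]
  }
  lib <- new_library(mol_ids, lab, mol_weight = mw,
                     structure = graphs, sdf = sdf_list)
  attr(lib, "failures") <- failures
  lib
}

#' Write a library to SDF + label CSV
#'
#' Writes one SDF record per molecule (first-conformer coordinates when an
#' ensemble exists, otherwise the stored coordinates) and a `mol_id,label`
#' CSV. Together with [read_labeled_library()] this round-trips ids, labels
#' and feature multisets.
#'
#' @param library Molecule library tibble with parsed structures.
#' @param structure_path,label_path Output paths.
#' @return Invisibly, the library.
#' @export
write_library <- function(library, structure_path, label_path) {
  assert_library(library)
  if (!"sdf" %in% names(library) || all(map_lgl(library$sdf, is.null))) {
    abort("library has no SDF structures to write; use write_feature_library() for feature clouds")
  }
  keep <- !map_lgl(library$sdf, is.null)
  sdfs <- library$sdf[keep]
  ids <- library$mol_id[keep]
  upd <- map(seq_along(sdfs), function(i) {
    sdf <- sdfs[[i]]
    confs <- library$conformers[which(keep)[i]][[1]]
    if (!is.null(confs) && nrow(confs) > 0) {
      cc <- confs[confs$conf_id == min(confs$conf_id), ]
      cc <- cc[order(cc$atom), ]
      ab <- ChemmineR::atomblock(sdf)
      heavy <- which(sub("_.*$", "", rownames(ab)) != "H")
      if (length(heavy) == nrow(cc)) {
        # 4-decimal fixed precision: V2000 coordinate fields must not use
        # scientific notation
        ab[heavy, 1] <- round(cc$x, 4)
        ab[heavy, 2] <- round(cc$y, 4)
        ab[heavy, 3] <- round(cc$z, 4)
        sdf@atomblock <- ab
      }
    }
    sdf@header["Molecule_Name"] <- ids[i]
    sdf
  })
  sdfset <- sdfset_from_list(upd, ids)
  ChemmineR::write.SDF(sdfset, file = structure_path, cid = TRUE)
  readr::write_csv(tibble(mol_id = library$mol_id, label = library$label),
                   label_path)
  invisible(library)
}

#' Write / read a feature-cloud library as CSV
#'
#' Feature-cloud libraries carry feature points but no chemistry. The CSV
#' has one row per feature: `mol_id, ftype, x, y, z, label` (plus
#' `mol_weight` when present). Round-trips exactly.
#'
#' @param library Feature-cloud library tibble.
#' @param path CSV path.
#' @return `write_feature_library()`: invisibly, the library.
#'   `read_feature_library()`: the library tibble.
#' @export
write_feature_library <- function(library, path) {
  assert_library(library)
  long <- map2(library$mol_id, library$features, function(id, ft) {
    if (is.null(ft) || nrow(ft) == 0) return(NULL)
    tibble(mol_id = id, ftype = ft$ftype, x = ft$x, y = ft$y, z = ft$z)
  }) |>
    list_rbind() |>
    left_join(
      tibble(mol_id = library$mol_id, label = library$label,
             mol_weight = library$mol_weight %||% NA_real_),
      by = "mol_id"
    )
  readr::write_csv(long, path)
  invisible(library)
}

#' @rdname write_feature_library
#' @export
read_feature_library <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  long <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("mol_id", "ftype", "x", "y", "z", "label")
  if (!all(need %in% names(long))) {
    abort(paste0("feature CSV must have columns ",
                 paste(need, collapse = ", ")))
  }
  check_labels(long$label)
  mols <- long |>
    distinct(.data$mol_id, .data$label,
             mol_weight = if ("mol_weight" %in% names(long)) .data$mol_weight else NA_real_)
  feats <- split(long, factor(long$mol_id, levels = mols$mol_id)) |>
    map(function(d) {
      tibble(conf_id = 1L, ftype = d$ftype, x = d$x, y = d$y, z = d$z)
    })
  tibble(
    mol_id = mols$mol_id,
    label = mols$label,
    mol_weight = mols$mol_weight,
    features = unname(feats)
  )
}
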