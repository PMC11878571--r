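# On-disk contract: dense delimited text or MatrixMarket matrices, TSV
# parcellation and cohort metadata. Everything downstream consumes the
# validated objects constructed here.

#' Construct a connectome object
#'
#' A connectome is a square, symmetric, nonnegative weighted adjacency
#' matrix of streamline counts between atlas parcels, with a zero diagonal
#' (self-connections are discarded), plus identifying metadata.
#'
#' @param matrix Square numeric matrix of nonnegative, finite edge weights.
#' @param parcel_ids Character vector of parcel identifiers, one per row.
#' @param scale Integer parcellation scale (1--5).
#' @param subject_id Subject identifier.
#' @param timepoint One of `"control"`, `"early"`, `"late"`.
#' @return An object of class `connectome`.
#' @export
connectome <- function(matrix, parcel_ids = NULL, scale = NA_integer_,
                       subject_id = NA_character_,
                       timepoint = c("control", "early", "late")) {
  timepoint <- match.arg(timepoint)
  matrix <- as.matrix(matrix)
  if (is.null(parcel_ids)) {
    parcel_ids <- if (!is.null(rownames(matrix))) rownames(matrix)
                  else sprintf("parcel_%03d", seq_len(nrow(matrix)))
  }
  obj <- structure(
    list(matrix = matrix, parcel_ids = as.character(parcel_ids),
         scale = as.integer(scale), subject_id = subject_id,
         timepoint = timepoint),
    class = "connectome")
  validate_connectome(obj)
}

#' Validate connectome invariants
#'
#' Checks squareness, parcel-id alignment, finiteness, nonnegativity,
#' symmetry (within 1e-9 relative Frobenius) and a zero diagonal.
#'
#' @param x A `connectome`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_connectome <- function(x) {
  w <- x$matrix
  if (!is.numeric(w) || length(dim(w)) != 2L || nrow(w) != ncol(w))
    stop("connectome matrix must be square and numeric", call. = FALSE)
  if (nrow(w) != length(x$parcel_ids))
    stop("parcel_ids length (", length(x$parcel_ids),
         ") does not match matrix dimension (", nrow(w), ")", call. = FALSE)
  if (any(!is.finite(w)))
    stop("connectome contains non-finite entries", call. = FALSE)
  if (any(w < 0))
    stop("connectome contains negative entries", call. = FALSE)
  if (relative_asymmetry(w) > 1e-9)
    stop("connectome matrix is not symmetric", call. = FALSE)
  if (any(diag(w) != 0))
    stop("connectome diagonal must be zero", call. = FALSE)
  invisible(x)
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("<connectome> %s/%s scale %s: %d parcels, total weight %.4g\n",
              x$subject_id, x$timepoint, x$scale, nrow(x$matrix),
              sum(x$matrix) / 2))
  invisible(x)
}

# Relative Frobenius asymmetry ||W - W'||_F / ||W||_F; 0 for an all-zero W.
relative_asymmetry <- function(w) {
  denom <- sqrt(sum(w^2))
  if (denom == 0) return(0)
  sqrt(sum((w - t(w))^2)) / denom
}

#' Read a connectivity matrix from disk
#'
#' Accepts dense delimited numeric text (comma or whitespace separated) and
#' MatrixMarket coordinate files (`.mtx`). Small floating-point asymmetry
#' (relative Frobenius norm at most `1e-6`) is repaired by averaging the
#' matrix with its transpose; anything larger is rejected as wrong data.
#' The diagonal is zeroed.
#'
#' @param path Path to the matrix file.
#' @param parcellation Optional `parcellation` whose parcel count the matrix
#'   must match (its parcel ids are attached in order).
#' @param scale,subject_id,timepoint Metadata passed to [connectome()].
#' @return A validated [connectome()].
#' @export
read_connectome <- function(path, parcellation = NULL, scale = NA_integer_,
                            subject_id = NA_character_,
                            timepoint = "control") {
  if (!file.exists(path)) stop("matrix file not found: ", path, call. = FALSE)
  w <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    as.matrix(Matrix::readMM(path))
  } else {
    first <- readLines(path, n = 1L)
    sep <- if (grepl(",", first, fixed = TRUE)) "," else ""
    as.matrix(read.table(path, header = FALSE, sep = sep,
                         colClasses = "numeric"))
  }
  dimnames(w) <- NULL
  if (nrow(w) != ncol(w))
    stop("matrix in ", path, " is not square (", nrow(w), "x", ncol(w), ")",
         call. = FALSE)
  if (!is.null(parcellation)) {
    if (nrow(w) != nrow(parcellation))
      stop("matrix dimension ", nrow(w), " does not match parcellation (",
           nrow(parcellation), " parcels): ", path, call. = FALSE)
    if (!is.na(scale) && !is.na(attr(parcellation, "scale")) &&
        scale != attr(parcellation, "scale"))
      stop("scale mismatch between matrix request and parcellation",
           call. = FALSE)
  }
  if (any(!is.finite(w)))
    stop("non-finite entries in ", path, call. = FALSE)
  if (any(w < 0))
    stop("negative entries in ", path, call. = FALSE)
  asym <- relative_asymmetry(w)
  if (asym > 1e-6)
    stop(sprintf("matrix in %s is asymmetric (relative asymmetry %.3g > 1e-6)",
                 path, asym), call. = FALSE)
  if (asym > 0) w <- (w + t(w)) / 2
  diag(w) <- 0
  connectome(w,
             parcel_ids = if (!is.null(parcellation)) parcellation$parcel_id,
             scale = scale, subject_id = subject_id, timepoint = timepoint)
}

#' Write a connectome matrix to disk
#'
#' Dense text is written at full double precision so that a write/read
#' round trip reproduces the matrix bit-exactly; `.mtx` paths are written
#' in MatrixMarket coordinate format.
#'
#' @param x A `connectome`.
#' @param path Output path; a `.mtx` suffix selects MatrixMarket.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  w <- x$matrix
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(w, sparse = TRUE),
                                            "generalMatrix"), "CsparseMatrix"),
                    path)
  } else {
    txt <- apply(w, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(txt, path)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Parcellation

.lobe_taxonomy_default <- c("frontal", "temporal", "parietal", "occipital",
                            "insular-cingulate")
.structure_classes <- c("cortical", "thalamic", "hippocampal", "brainstem",
                        "other-subcortical")

#' Read parcellation metadata
#'
#' The parcellation table maps each parcel to a hemisphere, a cortical lobe
#' (cortical parcels only) and a structure class. The atlas convention
#' enforced here: seven thalamic parcels per hemisphere, three hippocampal
#' parcels per hemisphere (head/body/tail) and four brainstem parcels, at
#' every scale; every cortical parcel belongs to exactly one lobe and the
#' lobes span ten (hemisphere, lobe) combinations.
#'
#' @param path TSV with header
#'   `parcel_id, name, hemisphere, lobe, structure_class`.
#' @param scale Parcellation scale the table describes.
#' @param lobes Lobe taxonomy (per hemisphere); defaults to frontal,
#'   temporal, parietal, occipital and insular-cingulate.
#' @return A `parcellation` data frame with a `scale` attribute.
#' @export
read_parcellation <- function(path, scale, lobes = .lobe_taxonomy_default) {
  if (!file.exists(path)) stop("parcellation file not found: ", path,
                               call. = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), quote = "")
  as_parcellation(df, scale = scale, lobes = lobes)
}

#' Construct and validate a parcellation
#'
#' @param df Data frame with columns `parcel_id`, `name`, `hemisphere`,
#'   `lobe`, `structure_class`.
#' @inheritParams read_parcellation
#' @return A validated `parcellation`.
#' @export
as_parcellation <- function(df, scale, lobes = .lobe_taxonomy_default) {
  required <- c("parcel_id", "name", "hemisphere", "lobe", "structure_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("parcellation table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$parcel_id))
    stop("duplicate parcel_id in parcellation", call. = FALSE)
  if (!all(df$hemisphere %in% c("left", "right", "midline")))
    stop("unknown hemisphere label in parcellation", call. = FALSE)
  if (!all(df$structure_class %in% .structure_classes))
    stop("unknown structure_class in parcellation", call. = FALSE)
  cort <- df$structure_class == "cortical"
  if (any(is.na(df$lobe[cort])))
    stop("cortical parcel without lobe assignment", call. = FALSE)
  if (!all(df$lobe[cort] %in% lobes))
    stop("unknown lobe label: ",
         paste(setdiff(df$lobe[cort], lobes), collapse = ", "), call. = FALSE)
  for (h in c("left", "right")) {
    n_thal <- sum(df$structure_class == "thalamic" & df$hemisphere == h)
    if (n_thal != 7L)
      stop("expected 7 thalamic parcels in ", h, " hemisphere, found ",
           n_thal, call. = FALSE)
    n_hipp <- sum(df$structure_class == "hippocampal" & df$hemisphere == h)
    if (n_hipp != 3L)
      stop("expected 3 hippocampal parcels in ", h, " hemisphere, found ",
           n_hipp, call. = FALSE)
  }
  if (sum(df$structure_class == "brainstem") != 4L)
    stop("expected 4 brainstem parcels, found ",
         sum(df$structure_class == "brainstem"), call. = FALSE)
  hl <- unique(df[cort, c("hemisphere", "lobe")])
  if (nrow(hl) != 10L)
    stop("expected 10 (hemisphere, lobe) combinations, found ", nrow(hl),
         call. = FALSE)
  rownames(df) <- NULL
  structure(df, scale = as.integer(scale), lobes = lobes,
            class = c("parcellation", "data.frame"))
}

#' Write parcellation metadata as TSV
#' @param p A `parcellation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_parcellation <- function(p, path) {
  write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Cohort

#' Read a cohort: metadata plus all connectivity matrices
#'
#' The metadata TSV has one row per subject-scan with header
#' `subject_id, group, timepoint, age_at_scan, sex, histopathology,
#' seizure_free, affected_lobe, affected_hemisphere`. Matrix files are
#' looked up in `matrix_dir` as `<subject_id>_<timepoint>_scale<k>` with
#' extension `.txt`, `.csv` or `.mtx`.
#'
#' Controls must have exactly one scan (timepoint `control`); patients
#' exactly two (`early` then `late`, with non-decreasing age) and a
#' recorded affected lobe.
#'
#' @param metadata_path Cohort metadata TSV.
#' @param matrix_dir Directory holding the matrix files.
#' @param scale Parcellation scale to load.
#' @param parcellation The scale's `parcellation`.
#' @param quiet Suppress the subject-count message.
#' @return A `cohort` object (see [new_cohort()]).
#' @export
read_cohort <- function(metadata_path, matrix_dir, scale, parcellation,
                        quiet = FALSE) {
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path, call. = FALSE)
  meta <- read.table(metadata_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE, na.strings = c("NA", ""),
                     quote = "")
  if (nrow(meta) == 0L) stop("no subjects in metadata", call. = FALSE)
  required <- c("subject_id", "group", "timepoint", "age_at_scan", "sex")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols))
    stop("metadata missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (opt in c("histopathology", "seizure_free", "affected_lobe",
                "affected_hemisphere"))
    if (is.null(meta[[opt]])) meta[[opt]] <- NA
  meta$seizure_free <- as.logical(meta$seizure_free)

  connectomes <- list()
  for (i in seq_len(nrow(meta))) {
    sid <- meta$subject_id[i]; tp <- meta$timepoint[i]
    stem <- file.path(matrix_dir, sprintf("%s_%s_scale%d", sid, tp, scale))
    candidates <- paste0(stem, c(".txt", ".csv", ".mtx"))
    hit <- candidates[file.exists(candidates)]
    if (!length(hit))
      stop("missing matrix file for subject ", sid, " timepoint ", tp,
           " at scale ", scale, call. = FALSE)
    connectomes[[paste(sid, tp, sep = "|")]] <-
      read_connectome(hit[1L], parcellation = parcellation, scale = scale,
                      subject_id = sid, timepoint = tp)
  }
  cohort <- new_cohort(scans = meta, connectomes = connectomes,
                       parcellation = parcellation, scale = scale)
  if (!quiet)
    message(sprintf("cohort loaded: %d controls, %d patients (%d scans)",
                    sum(cohort$subjects$group == "control"),
                    sum(cohort$subjects$group == "patient"), nrow(meta)))
  cohort
}

#' Construct a cohort from in-memory pieces
#'
#' @param scans Data frame, one row per subject-scan (see [read_cohort()]
#'   for the columns).
#' @param connectomes Named list of [connectome()] objects keyed
#'   `"<subject_id>|<timepoint>"`.
#' @param parcellation The scale's `parcellation`.
#' @param scale Parcellation scale.
#' @return A validated `cohort`: list with elements `scans`, `subjects`
#'   (one row per subject), `connectomes`, `parcellation`, `scale`.
#' @export
new_cohort <- function(scans, connectomes, parcellation, scale) {
  scans <- as.data.frame(scans, stringsAsFactors = FALSE)
  if (!all(scans$group %in% c("control", "patient")))
    stop("group must be 'control' or 'patient'", call. = FALSE)
  if (!all(scans$sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  subjects <- do.call(rbind, lapply(split(scans, scans$subject_id), function(s) {
    sid <- s$subject_id[1L]
    if (s$group[1L] == "control") {
      if (nrow(s) != 1L || s$timepoint[1L] != "control")
        stop("control ", sid, " must have exactly one 'control' scan",
             call. = FALSE)
    } else {
      if (nrow(s) != 2L || !setequal(s$timepoint, c("early", "late")))
        stop("patient ", sid, " must have exactly an 'early' and a 'late' scan",
             call. = FALSE)
      if (s$age_at_scan[s$timepoint == "early"] >
          s$age_at_scan[s$timepoint == "late"])
        stop("patient ", sid, " has early age greater than late age",
             call. = FALSE)
      if (is.na(s$affected_lobe[1L]) || is.na(s$affected_hemisphere[1L]))
        stop("patient ", sid, " is missing affected lobe/hemisphere",
             call. = FALSE)
    }
    data.frame(subject_id = sid, group = s$group[1L], sex = s$sex[1L],
               histopathology = s$histopathology[1L],
               seizure_free = s$seizure_free[1L],
               affected_lobe = s$affected_lobe[1L],
               affected_hemisphere = s$affected_hemisphere[1L],
               stringsAsFactors = FALSE)
  }))
  rownames(subjects) <- NULL
  for (i in seq_len(nrow(scans))) {
    key <- paste(scans$subject_id[i], scans$timepoint[i], sep = "|")
    cn <- connectomes[[key]]
    if (is.null(cn))
      stop("missing connectome for ", key, call. = FALSE)
    if (!identical(cn$parcel_ids, parcellation$parcel_id))
      stop("parcel ordering mismatch for ", key, call. = FALSE)
  }
  structure(list(scans = scans, subjects = subjects,
                 connectomes = connectomes, parcellation = parcellation,
                 scale = as.integer(scale)),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> scale %d: %d controls, %d patients, %d connectomes of %d parcels\n",
              x$scale, sum(x$subjects$group == "control"),
              sum(x$subjects$group == "patient"), length(x$connectomes),
              nrow(x$parcellation)))
  invisible(x)
}

#' Fetch one connectome from a cohort
#' @param cohort A `cohort`.
#' @param subject_id,timepoint Scan key.
#' @return The [connectome()].
#' @export
cohort_connectome <- function(cohort, subject_id, timepoint) {
  cn <- cohort$connectomes[[paste(subject_id, timepoint, sep = "|")]]
  if (is.null(cn))
    stop("no connectome for ", subject_id, " at ", timepoint, call. = FALSE)
  cn
}

#' Write a cohort to disk in the package's on-disk formats
#'
#' Emits the metadata TSV, the parcellation TSV and one dense-text matrix
#' per scan, named `<subject_id>_<timepoint>_scale<k>.txt`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.table(cohort$scans, file.path(dir, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, na = "NA")
  write_parcellation(cohort$parcellation,
                     file.path(dir, sprintf("parcellation_scale%d.tsv",
                                            cohort$scale)))
  for (key in names(cohort$connectomes)) {
    cn <- cohort$connectomes[[key]]
    write_connectome(cn, file.path(dir, sprintf("%s_%s_scale%d.txt",
                                                cn$subject_id, cn$timepoint,
                                                cohort$scale)))
  }
  invisible(dir)
}
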