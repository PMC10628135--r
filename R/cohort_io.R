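# Reading, binarising and filtering mutation and clinical survival data.
#
# Mutation profiles are stored as a plain integer matrix (patients in rows,
# genes in columns, cells 0/1) with row and column names carrying the
# identifiers; survival tables are data.frames with columns patient_id,
# time (overall survival, months) and event (1 = deceased, 0 = censored).

#' Construct and validate a binary mutation matrix
#'
#' @param values numeric or integer matrix with patient identifiers as row
#'   names and gene symbols as column names; every cell must be 0 or 1.
#' @return an integer matrix of class `mutation_matrix`.
#' @export
mutation_matrix <- function(values) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("mutation matrix needs patient row names and gene column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate patient identifiers in mutation matrix")
  if (anyDuplicated(colnames(values)))
    stop("duplicate gene symbols in mutation matrix")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(values)) + 1
    j <- ((bad[1] - 1) %/% nrow(values)) + 1
    stop(sprintf("non-binary cell at patient '%s', gene '%s': %s",
                 rownames(values)[i], colnames(values)[j],
                 as.character(values[bad[1]])))
  }
  storage.mode(values) <- "integer"
  colnames(values) <- toupper(colnames(values))
  class(values) <- c("mutation_matrix", class(values))
  values
}

#' Read a binary mutation matrix from disk
#'
#' Two layouts are supported. `layout = "matrix"` expects a TSV whose first
#' column holds patient identifiers, whose header row holds gene symbols and
#' whose cells are 0/1. `layout = "maf"` expects one mutation call per row
#' with at least the columns `Tumor_Sample_Barcode` and `Hugo_Symbol`; any
#' patient-gene pair with one or more calls becomes a 1 and duplicate calls
#' collapse. Mutation type is deliberately discarded: only presence/absence
#' of a somatic mutation enters the model.
#'
#' @param path path to a TSV file.
#' @param layout `"matrix"` or `"maf"`.
#' @param patient_roster optional character vector of patient identifiers;
#'   in `maf` layout, patients on the roster with zero calls are retained as
#'   all-zero rows.
#' @return a [mutation_matrix].
#' @export
read_mutation_matrix <- function(path, layout = c("matrix", "maf"),
                                 patient_roster = NULL) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "matrix") {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             check.names = FALSE, comment.char = "#",
                             stringsAsFactors = FALSE)
    ids <- as.character(tab[[1]])
    vals <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(vals))
      stop("non-numeric cell in mutation matrix file ", path)
    rownames(vals) <- ids
    return(mutation_matrix(vals))
  }
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("Tumor_Sample_Barcode", "Hugo_Symbol")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("MAF-style input is missing required column(s): ",
         paste(miss, collapse = ", "))
  patients <- sort(unique(c(as.character(tab$Tumor_Sample_Barcode),
                            as.character(patient_roster))))
  genes <- sort(unique(toupper(as.character(tab$Hugo_Symbol))))
  vals <- matrix(0L, length(patients), length(genes),
                 dimnames = list(patients, genes))
  vals[cbind(match(as.character(tab$Tumor_Sample_Barcode), patients),
             match(toupper(as.character(tab$Hugo_Symbol)), genes))] <- 1L
  mutation_matrix(vals)
}

#' Read a clinical survival table (cBioPortal dialect)
#'
#' Expects tab-separated columns `PATIENT_ID`, `OS_MONTHS` and `OS_STATUS`;
#' lines starting with `#` are skipped. Status tokens such as
#' `"1:DECEASED"` / `"0:LIVING"`, bare `0`/`1`, or `DECEASED`/`LIVING` are
#' mapped to the event indicator. Rows with missing time or status are
#' dropped with a message.
#'
#' @param path path to the clinical TSV.
#' @param cancer_type_allowlist optional character vector; when given and a
#'   `CANCER_TYPE` column is present, patients whose type is not on the list
#'   (e.g. those labelled unknown) are dropped before any analysis, with a
#'   message.
#' @return data.frame with columns `patient_id`, `time`, `event` (plus
#'   `cancer_type` when the input has one).
#' @export
read_survival <- function(path, cancer_type_allowlist = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  need <- c("PATIENT_ID", "OS_MONTHS", "OS_STATUS")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "))
  if (!is.null(cancer_type_allowlist) && "CANCER_TYPE" %in% names(tab)) {
    keep <- tab$CANCER_TYPE %in% cancer_type_allowlist
    if (any(!keep))
      message(sum(!keep), " patient(s) outside the cancer-type allowlist dropped")
    tab <- tab[keep, , drop = FALSE]
  }
  id <- as.character(tab$PATIENT_ID)
  time <- suppressWarnings(as.numeric(tab$OS_MONTHS))
  status <- trimws(as.character(tab$OS_STATUS))
  drop <- is.na(time) | is.na(status) | status == ""
  if (any(drop))
    message(sum(drop), " record(s) dropped for missing OS time or status")
  id <- id[!drop]; time <- time[!drop]; status <- status[!drop]
  if (any(time < 0))
    stop("negative survival time for patient(s): ",
         paste(id[time < 0], collapse = ", "))
  event <- map_os_status(status)
  out <- data.frame(patient_id = id, time = time, event = event,
                    stringsAsFactors = FALSE)
  if ("CANCER_TYPE" %in% names(tab))
    out$cancer_type <- as.character(tab$CANCER_TYPE)[!drop]
  out
}

map_os_status <- function(status) {
  tok <- toupper(status)
  out <- rep(NA_integer_, length(tok))
  out[tok %in% c("1:DECEASED", "DECEASED", "1", "1:DEAD", "DEAD")] <- 1L
  out[tok %in% c("0:LIVING", "LIVING", "0", "0:ALIVE", "ALIVE",
                 "0:CENSORED", "CENSORED")] <- 0L
  if (anyNA(out))
    stop("unmappable OS_STATUS token(s): ",
         paste(unique(status[is.na(out)]), collapse = ", "))
  out
}

#' Remove rarely mutated genes
#'
#' Drops every gene mutated in at most `ceiling(min_fraction * n_patients)`
#' patients. With the default 1% threshold on a 1571-patient cohort this
#' removes genes mutated in 16 or fewer patients. Column order of the
#' survivors is preserved.
#'
#' @param m a [mutation_matrix].
#' @param min_fraction minimum mutated fraction of the cohort, in (0, 1).
#' @return list with elements `matrix` (the filtered [mutation_matrix]) and
#'   `removed` (character vector of dropped gene symbols).
#' @export
filter_rare_genes <- function(m, min_fraction = 0.01) {
  stopifnot(min_fraction > 0, min_fraction < 1)
  counts <- colSums(m)
  cutoff <- ceiling(min_fraction * nrow(m))
  keep <- counts > cutoff
  if (!any(keep))
    stop("all genes fall at or below the rarity cutoff (", cutoff,
         " patients); lower min_fraction")
  list(matrix = mutation_matrix(unclass(m)[, keep, drop = FALSE]),
       removed = colnames(m)[!keep])
}

#' Join a mutation matrix with a survival table
#'
#' Restricts both inputs to the intersection of patient identifiers and
#' orders them identically (sorted ids), so downstream code can rely on
#' positional alignment.
#'
#' @param m a [mutation_matrix].
#' @param surv a survival data.frame from [read_survival()].
#' @return list with aligned `mutations` and `survival` components.
#' @export
join_cohort <- function(m, surv) {
  ids <- sort(intersect(rownames(m), surv$patient_id))
  if (!length(ids)) stop("no patients shared between mutation and survival data")
  list(
    mutations = mutation_matrix(unclass(m)[ids, , drop = FALSE]),
    survival = surv[match(ids, surv$patient_id), , drop = FALSE]
  )
}
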