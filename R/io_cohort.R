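# Cohort table I/O: a TSV of per-subject covariates plus per-subject GIFTI
# vertex maps referenced by relative path.

#' Write a cohort to a directory (TSV + per-subject GIFTI maps)
#'
#' @param cohort a `cohort_table`.
#' @param dir output directory (created if needed).
#' @return the path of the written TSV, invisibly.
#' @export
write_cohort_tsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cov <- cohort$covariates
  ficd_files <- sprintf("%s_ficd.gii", cov$id)
  gm_files <- sprintf("%s_gmvol.gii", cov$id)
  for (i in seq_len(nrow(cov))) {
    write_vertex_map(cohort$ficd[, i], file.path(dir, ficd_files[i]))
    write_vertex_map(cohort$gmvol[, i], file.path(dir, gm_files[i]))
  }
  write_surface(cohort$mesh, file.path(dir, "mesh.gii"))
  tab <- data.frame(id = cov$id, group = as.character(cov$group),
                    severity = cov$severity, tbv = cov$tbv,
                    ficd_map = ficd_files, gm_map = gm_files,
                    stringsAsFactors = FALSE)
  path <- file.path(dir, "cohort.tsv")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cohort from a TSV written by [write_cohort_tsv()]
#'
#' @param path the `cohort.tsv` file; maps are resolved relative to it.
#' @param mesh optional `surface_mesh`; defaults to `mesh.gii` next to the
#'   TSV. Map lengths are validated against it.
#' @return a `cohort_table`.
#' @export
read_cohort_tsv <- function(path, mesh = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("id", "group", "severity", "tbv", "ficd_map", "gm_map")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("cohort TSV lacks columns: ", paste(missing_cols, collapse = ", "))
  bad <- which(is.na(tab$group) | tab$group == "")
  if (length(bad))
    stop("missing group label in cohort TSV row(s): ",
         paste(bad, collapse = ", "))
  groups <- unique(tab$group)
  if (length(groups) != 2L)
    stop("cohort must have exactly two group levels, got: ",
         paste(groups, collapse = ", "))
  dir <- dirname(path)
  if (is.null(mesh)) mesh <- read_surface(file.path(dir, "mesh.gii"))
  nv <- n_vertices(mesh)
  ficd <- sapply(tab$ficd_map, function(f)
    read_vertex_map(file.path(dir, f), mesh))
  gmvol <- sapply(tab$gm_map, function(f)
    read_vertex_map(file.path(dir, f), mesh))
  dim(ficd) <- c(nv, nrow(tab)); dim(gmvol) <- c(nv, nrow(tab))
  colnames(ficd) <- tab$id; colnames(gmvol) <- tab$id
  structure(list(mesh = mesh, ficd = ficd, gmvol = gmvol,
                 covariates = data.frame(id = tab$id,
                                         group = factor(tab$group),
                                         severity = tab$severity,
                                         tbv = tab$tbv,
                                         stringsAsFactors = FALSE),
                 spec = NULL),
            class = "cohort_table")
}
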