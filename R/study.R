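#' Assemble a hierarchical multitype point-pattern study
#'
#' A study bundles a table of segmented-cell records (coordinates in
#' micrometres, cell-type label, image identity) with the image -> patient
#' -> cohort hierarchy and one rectangular observation window per image.
#' Windows are closed (boundary points are inside) and axis-aligned; if
#' none are supplied the per-image bounding box is used, which is adequate
#' for exploration but users should pass true image extents because
#' intensity integrals depend on window area.
#'
#' @param cells A data frame with columns `x`, `y`, `cell_type`,
#'   `image_id`, `patient_id`, `cohort_id` (names remappable via `schema`).
#' @param windows Optional data frame with columns `image_id`, `x_min`,
#'   `x_max`, `y_min`, `y_max`; one row per image. Images absent from
#'   `windows` get their bounding box.
#' @param schema Named character vector mapping the canonical column names
#'   to the names used in `cells`, e.g. `c(x = "X_um", cell_type = "type")`.
#' @return An object of class `sic_study`: a list with tibbles `cells`,
#'   `windows` and `hierarchy` (one row per image with `patient_id`,
#'   `cohort_id`).
#' @examples
#' cells <- tibble::tibble(
#'   x = c(10, 20, 30), y = c(10, 20, 30), cell_type = c("T", "B", "T"),
#'   image_id = "img1", patient_id = "pat1", cohort_id = "grp1")
#' sic_study(cells)
#' @export
sic_study <- function(cells, windows = NULL, schema = NULL) {
  canonical <- c("x", "y", "cell_type", "image_id", "patient_id", "cohort_id")
  cells <- tibble::as_tibble(cells)
  if (!is.null(schema)) {
    bad <- setdiff(names(schema), canonical)
    if (length(bad)) {
      stop("Unknown schema entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(cells)) {
        stop(sprintf("Column '%s' (mapped to '%s') not found.",
                     schema[[canon]], canon), call. = FALSE)
      }
      names(cells)[names(cells) == schema[[canon]]] <- canon
    }
  }
  missing_cols <- setdiff(canonical, names(cells))
  if (length(missing_cols)) {
    stop("Missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  cells <- dplyr::mutate(
    cells[canonical],
    x = as.numeric(.data$x), y = as.numeric(.data$y),
    dplyr::across(dplyr::all_of(c("cell_type", "image_id", "patient_id",
                                  "cohort_id")), as.character))
  if (anyNA(cells$x) || anyNA(cells$y)) {
    stop("Coordinates must be numeric and non-missing.", call. = FALSE)
  }

  hierarchy <- dplyr::distinct(cells, .data$image_id, .data$patient_id,
                               .data$cohort_id)
  dup_img <- hierarchy$image_id[duplicated(hierarchy$image_id)]
  if (length(dup_img)) {
    stop("Image(s) mapped to more than one patient/cohort: ",
         paste(unique(dup_img), collapse = ", "), call. = FALSE)
  }
  dup_pat <- dplyr::distinct(hierarchy, .data$patient_id, .data$cohort_id)
  dup_pat <- dup_pat$patient_id[duplicated(dup_pat$patient_id)]
  if (length(dup_pat)) {
    stop("Patient(s) mapped to more than one cohort: ",
         paste(unique(dup_pat), collapse = ", "), call. = FALSE)
  }

  bbox <- dplyr::summarise(
    dplyr::group_by(cells, .data$image_id),
    x_min = min(.data$x), x_max = max(.data$x),
    y_min = min(.data$y), y_max = max(.data$y), .groups = "drop")
  if (is.null(windows)) {
    windows <- bbox
  } else {
    windows <- tibble::as_tibble(windows)
    need <- c("image_id", "x_min", "x_max", "y_min", "y_max")
    if (!all(need %in% names(windows))) {
      stop("`windows` must have columns ", paste(need, collapse = ", "),
           call. = FALSE)
    }
    windows <- dplyr::mutate(windows[need],
                             image_id = as.character(.data$image_id))
    windows <- dplyr::bind_rows(
      windows,
      dplyr::anti_join(bbox, windows, by = "image_id"))
  }
  if (any(windows$x_max <= windows$x_min) ||
      any(windows$y_max <= windows$y_min)) {
    stop("Each window must satisfy x_max > x_min and y_max > y_min.",
         call. = FALSE)
  }
  chk <- dplyr::left_join(cells, windows, by = "image_id")
  outside <- chk$x < chk$x_min | chk$x > chk$x_max |
    chk$y < chk$y_min | chk$y > chk$y_max
  if (any(outside)) {
    stop(sprintf("%d cell(s) fall outside their image window.",
                 sum(outside)), call. = FALSE)
  }

  structure(list(cells = cells,
                 windows = dplyr::arrange(windows, .data$image_id),
                 hierarchy = dplyr::arrange(hierarchy, .data$image_id)),
            class = "sic_study")
}

#' @export
print.sic_study <- function(x, ...) {
  cat(sprintf(
    "<sic_study> %d cells, %d types, %d images, %d patients, %d cohorts\n",
    nrow(x$cells), dplyr::n_distinct(x$cells$cell_type),
    nrow(x$hierarchy), dplyr::n_distinct(x$hierarchy$patient_id),
    dplyr::n_distinct(x$hierarchy$cohort_id)))
  invisible(x)
}

window_area <- function(w) (w$x_max - w$x_min) * (w$y_max - w$y_min)

#' Read / write a cell table in delimited-text form
#'
#' `read_cells()` loads a CSV of segmented cells (plus an optional window
#' CSV) into a [sic_study()]; `write_cells()` writes the study back in the
#' same dialect so that write-then-read round-trips exactly.
#'
#' @param path Path to the cell CSV.
#' @param windows_path Optional path to a window CSV with columns
#'   `image_id`, `x_min`, `x_max`, `y_min`, `y_max`.
#' @param schema Optional column-name mapping, as in [sic_study()].
#' @return `read_cells()` returns a `sic_study`; `write_cells()` returns
#'   `path` invisibly.
#' @export
read_cells <- function(path, windows_path = NULL, schema = NULL) {
  cells <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  windows <- if (!is.null(windows_path)) {
    readr::read_csv(windows_path, show_col_types = FALSE, progress = FALSE)
  }
  sic_study(cells, windows = windows, schema = schema)
}

#' @rdname read_cells
#' @param study A `sic_study` object.
#' @export
write_cells <- function(study, path, windows_path = NULL) {
  stopifnot(inherits(study, "sic_study"))
  readr::write_csv(study$cells, path, progress = FALSE)
  if (!is.null(windows_path)) {
    readr::write_csv(study$windows, windows_path, progress = FALSE)
  }
  invisible(path)
}

#' Restrict a study or cell table to one cell type
#'
#' @param study A `sic_study` or a cell tibble.
#' @param label A cell-type label present in the study's label set.
#' @return Same class as the input, containing only cells of that type
#'   (possibly zero rows); windows and hierarchy are unchanged.
#' @export
subset_type <- function(study, label) {
  cells <- if (inherits(study, "sic_study")) study$cells else study
  if (!label %in% unique(cells$cell_type)) {
    stop(sprintf("Unknown cell type '%s'.", label), call. = FALSE)
  }
  kept <- dplyr::filter(cells, .data$cell_type == label)
  if (inherits(study, "sic_study")) {
    out <- study
    out$cells <- kept
    out
  } else {
    kept
  }
}

#' Validate a study's hierarchy and tabulate its composition
#'
#' Checks that every image maps to exactly one patient and every patient
#' to one cohort, and reports per-image type counts and per-patient image
#' counts.
#'
#' @param study A `sic_study`.
#' @param hierarchy Optional external hierarchy tibble (`image_id`,
#'   `patient_id`, `cohort_id`) to validate against; images present in the
#'   cells but absent from it are orphans and raise an error.
#' @return A list with tibbles `images_per_patient`, `patients_per_cohort`
#'   and `type_counts` (image x type long counts), plus scalar totals.
#' @export
validate_study <- function(study, hierarchy = NULL) {
  stopifnot(inherits(study, "sic_study"))
  hier <- if (is.null(hierarchy)) study$hierarchy else
    tibble::as_tibble(hierarchy)
  orphan <- setdiff(unique(study$cells$image_id), hier$image_id)
  if (length(orphan)) {
    stop("Image(s) missing from the hierarchy map: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(hier$image_id)) {
    stop("Hierarchy maps an image to more than one patient.", call. = FALSE)
  }
  ipp <- dplyr::count(hier, .data$patient_id, name = "n_images")
  ppc <- dplyr::count(dplyr::distinct(hier, .data$patient_id,
                                      .data$cohort_id),
                      .data$cohort_id, name = "n_patients")
  tc <- dplyr::count(study$cells, .data$image_id, .data$cell_type,
                     name = "n_cells")
  list(images_per_patient = ipp,
       patients_per_cohort = ppc,
       type_counts = tc,
       n_images = nrow(hier),
       n_patients = nrow(ipp),
       n_cohorts = nrow(ppc),
       n_cells = nrow(study$cells))
}
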