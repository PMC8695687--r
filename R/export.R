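SCHEMA_VERSION <- "1.0"

#' Assign labels and channel numbers to electrodes
#'
#' Applies a two-column mapping (`label`, `channel`) to an electrode set by
#' row order or by an explicit `id` column in the mapping. This replaces the
#' interactive assignment table of a GUI workflow.
#'
#' @param electrodes An [electrode_set()].
#' @param mapping data.frame with columns `label` and `channel`, and
#'   optionally `id` (electrode ids; defaults to row order).
#' @return The electrode set with `label` and `channel` filled in.
#' @export
assign_channels <- function(electrodes, mapping) {
  mapping <- as.data.frame(mapping)
  if (!all(c("label", "channel") %in% names(mapping)))
    stop("mapping needs columns 'label' and 'channel'")
  ids <- if ("id" %in% names(mapping)) mapping$id else
    electrodes$id[seq_len(nrow(mapping))]
  m <- match(ids, electrodes$id)
  if (anyNA(m)) stop("mapping refers to unknown electrode ids")
  electrodes$label[m] <- as.character(mapping$label)
  electrodes$channel[m] <- as.integer(mapping$channel)
  electrodes
}

#' Export electrodes as channel-sorted tables
#'
#' Writes an analysis-ready session to `dir`:
#' \describe{
#'   \item{electrodes.tsv}{one row per contact in the electrode set's own
#'     order, BIDS-iEEG-style core columns (`name`, `x`, `y`, `z`, `size`)
#'     plus channel, MNI coordinates, tissue class and per-atlas modal
#'     labels;}
#'   \item{channel_map.tsv}{the same rows sorted by channel number, so row
#'     index equals channel, which is the table to join against recorded
#'     data;}
#'   \item{electrodes.json}{sidecar with the probabilistic label lists and
#'     provenance (schema and package version).}
#' }
#'
#' @param electrodes An [electrode_set()]; all contacts need channels unless
#'   `allow_unassigned`.
#' @param dir Output directory (created if needed).
#' @param allow_unassigned Permit contacts without channel numbers (they are
#'   omitted from `channel_map.tsv`).
#' @return `dir`, invisibly.
#' @export
export_channel_map <- function(electrodes, dir, allow_unassigned = FALSE) {
  ch <- electrodes$channel
  if (!allow_unassigned && anyNA(ch))
    stop("unassigned electrodes: ",
         paste(electrodes$id[is.na(ch)], collapse = ", "),
         " (use allow_unassigned = TRUE to export anyway)")
  dup <- unique(ch[!is.na(ch)][duplicated(ch[!is.na(ch)])])
  if (length(dup) > 0) {
    offenders <- electrodes$label[ch %in% dup]
    stop("duplicate channels ", paste(dup, collapse = ", "),
         " assigned to: ", paste(offenders, collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  df <- as.data.frame(electrodes)
  out <- data.frame(name = df$label, x = df$x, y = df$y, z = df$z,
                    size = df$radius_mm, channel = df$channel,
                    mni_x = df$mni_x, mni_y = df$mni_y, mni_z = df$mni_z,
                    tissue_class = df$tissue_class,
                    mean_intensity = df$mean_intensity,
                    id = df$id, stringsAsFactors = FALSE)
  for (nm in grep("^atlas_", names(df), value = TRUE)) out[[nm]] <- df[[nm]]
  extra <- setdiff(names(df), c("id", "x", "y", "z", "radius_mm", "label",
                                "channel", "tissue_class", "mean_intensity",
                                "mni_x", "mni_y", "mni_z",
                                grep("^atlas_", names(df), value = TRUE)))
  for (nm in extra) out[[nm]] <- df[[nm]]

  write_tsv <- function(d, path)
    write.table(format(d, digits = 17, trim = TRUE, scientific = FALSE),
                path, sep = "\t", quote = FALSE, row.names = FALSE,
                na = "n/a")
  write_tsv(out, file.path(dir, "electrodes.tsv"))
  cm <- out[!is.na(out$channel), , drop = FALSE]
  cm <- cm[order(cm$channel), , drop = FALSE]
  write_tsv(cm, file.path(dir, "channel_map.tsv"))

  pl <- attr(electrodes, "prob_labels")
  sidecar <- list(
    schema_version = SCHEMA_VERSION,
    software = "electrolocate",
    version = as.character(utils::packageVersion("electrolocate")),
    coordinate_units = "mm",
    prob_labels = if (is.null(pl)) NULL else
      lapply(pl, function(atlas_list)
        lapply(seq_along(atlas_list), function(q)
          list(id = electrodes$id[q],
               labels = atlas_list[[q]]))))
  jsonlite::write_json(sidecar, file.path(dir, "electrodes.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(dir)
}

#' Reload an exported session
#'
#' Reconstructs an [electrode_set()] (including probabilistic labels) from a
#' directory written by [export_channel_map()]. Unknown extra columns are
#' preserved; a missing `tissue_class` column loads as unset with a warning.
#'
#' @param dir Session directory.
#' @return An `eloc_electrodes` data.frame.
#' @export
load_session <- function(dir) {
  tsv <- file.path(dir, "electrodes.tsv")
  if (!file.exists(tsv)) stop("no electrodes.tsv in ", dir)
  lines <- readLines(tsv)
  ncol_hdr <- length(strsplit(lines[1], "\t", fixed = TRUE)[[1]])
  nfield <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  bad <- which(nfield != ncol_hdr)
  if (length(bad) > 0)
    stop("corrupted TSV row at line ", bad[1], " of ", tsv)
  df <- read.delim(tsv, stringsAsFactors = FALSE, na.strings = "n/a")

  side <- file.path(dir, "electrodes.json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else NULL
  if (!is.null(meta) && !is.null(meta$schema_version) &&
      meta$schema_version != SCHEMA_VERSION)
    stop("schema-version mismatch: file has ", meta$schema_version,
         ", this package reads ", SCHEMA_VERSION,
         "; migrate the session first")

  es <- electrode_set(x = df$x, y = df$y, z = df$z,
                      mean_intensity = df$mean_intensity,
                      radius_mm = df$size)
  es$id <- if (!is.null(df$id)) df$id else seq_len(nrow(df))
  es$label <- as.character(df$name)
  es$channel <- as.integer(df$channel)
  if (is.null(df$tissue_class)) {
    warning("tissue_class column missing; classes left unset")
  } else es$tissue_class <- as.character(df$tissue_class)
  for (nm in c("mni_x", "mni_y", "mni_z"))
    if (!is.null(df[[nm]])) es[[nm]] <- df[[nm]]
  known <- c("name", "x", "y", "z", "size", "channel", "mni_x", "mni_y",
             "mni_z", "tissue_class", "mean_intensity", "id")
  for (nm in setdiff(names(df), known)) es[[nm]] <- df[[nm]]

  if (!is.null(meta$prob_labels)) {
    pl <- lapply(meta$prob_labels, function(atlas_list)
      lapply(atlas_list, function(e) {
        d <- do.call(rbind, lapply(e$labels, function(r)
          data.frame(label = r$label, index = as.integer(r$index),
                     fraction = as.double(r$fraction),
                     stringsAsFactors = FALSE)))
        if (is.null(d)) data.frame(label = character(0), index = integer(0),
                                   fraction = double(0)) else d
      }))
    attr(es, "prob_labels") <- pl
  }
  es
}
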