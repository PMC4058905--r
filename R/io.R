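# Minimal NIfTI-1 (.nii, single-file, uncompressed) reader/writer. Only the
# fields this pipeline needs are honored: dim, datatype, pixdim (including
# TR), vox_offset, scl_slope/inter. Written files are little-endian float32
# or int32; the reader additionally accepts float64, int16 and uint8 and
# byte-swapped files.

.nifti_types <- data.frame(
  code = c(2L, 4L, 8L, 16L, 64L),
  what = c("integer", "integer", "integer", "double", "double"),
  size = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE)
)

write_padded_char <- function(con, s, n) {
  r <- raw(n)
  b <- charToRaw(s)
  stopifnot(length(b) <= n)
  r[seq_along(b)] <- b
  writeBin(r, con)
}

#' Write a 3-D or 4-D array as a NIfTI-1 volume
#'
#' @param img numeric array with 3 or 4 dimensions.
#' @param path output `.nii` path.
#' @param pixdim voxel sizes in mm (length 3).
#' @param tr repetition time in seconds (stored in `pixdim[4]`).
#' @param datatype `"float32"` (default) or `"int32"`.
#' @return `path`, invisibly.
#' @export
write_nifti <- function(img, path, pixdim = c(1, 1, 1), tr = 2,
                        datatype = c("float32", "int32")) {
  datatype <- match.arg(datatype)
  dm <- dim(img)
  if (is.null(dm) || !(length(dm) %in% c(3L, 4L))) {
    stop("`img` must be a 3-D or 4-D array", call. = FALSE)
  }
  code <- if (datatype == "float32") 16L else 8L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(348L, con, size = 4, endian = "little")
  writeBin(raw(34), con)                # data_type, db_name, extents, ...
  writeBin(charToRaw("r"), con)                            # regular
  writeBin(raw(1), con)                                    # dim_info
  dimfield <- c(length(dm), dm, rep(1L, 7L - length(dm)))
  writeBin(as.integer(dimfield), con, size = 2, endian = "little")
  writeBin(numeric(3), con, size = 4, endian = "little")   # intent_p1..3
  writeBin(0L, con, size = 2, endian = "little")           # intent_code
  writeBin(code, con, size = 2, endian = "little")         # datatype
  writeBin(if (datatype == "float32") 32L else 32L, con, size = 2,
           endian = "little")                              # bitpix
  writeBin(0L, con, size = 2, endian = "little")           # slice_start
  pd <- c(1, pixdim, tr, 0, 0, 0)
  writeBin(as.numeric(pd), con, size = 4, endian = "little")
  writeBin(352, con, size = 4, endian = "little")          # vox_offset
  writeBin(c(1, 0), con, size = 4, endian = "little")      # scl_slope/inter
  writeBin(0L, con, size = 2, endian = "little")           # slice_end
  writeBin(raw(1), con)                                    # slice_code
  writeBin(as.raw(10L), con)                               # xyzt: mm + s
  writeBin(numeric(4), con, size = 4, endian = "little")   # cal/slice/toff
  writeBin(integer(2), con, size = 4, endian = "little")   # glmax/glmin
  write_padded_char(con, "invisidec", 80)                  # descrip
  writeBin(raw(24), con)                                   # aux_file
  writeBin(c(0L, 0L), con, size = 2, endian = "little")    # q/sform_code
  writeBin(numeric(6), con, size = 4, endian = "little")   # quatern/qoffset
  srows <- rbind(c(pixdim[1], 0, 0, 0), c(0, pixdim[2], 0, 0),
                 c(0, 0, pixdim[3], 0))
  writeBin(as.numeric(t(srows)), con, size = 4, endian = "little")
  writeBin(raw(16), con)                                   # intent_name
  write_padded_char(con, "n+1", 4)                         # magic
  writeBin(raw(4), con)                                    # extender
  if (datatype == "float32") {
    writeBin(as.numeric(img), con, size = 4, endian = "little")
  } else {
    writeBin(as.integer(img), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Read a NIfTI-1 volume
#'
#' @param path a single-file uncompressed `.nii` path.
#' @return list with `data` (array), `pixdim` (length 3), `tr` (seconds) and
#'   `datatype` code.
#' @export
read_nifti <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_size <- readBin(con, "integer", 1, size = 4, endian = "little")
  endian <- "little"
  if (hdr_size != 348L) {
    endian <- "big"
    seek(con, 0)
    hdr_size <- readBin(con, "integer", 1, size = 4, endian = endian)
    if (hdr_size != 348L) {
      stop("not a NIfTI-1 file: ", path, call. = FALSE)
    }
  }
  seek(con, 40)
  dm <- readBin(con, "integer", 8, size = 2, endian = endian)
  ndim <- dm[1L]
  if (ndim < 3L || ndim > 4L) {
    stop("unsupported NIfTI dimensionality: ", ndim, call. = FALSE)
  }
  dims <- dm[2:(1 + ndim)]
  seek(con, 70)
  dtcode <- readBin(con, "integer", 1, size = 2, endian = endian)
  spec <- .nifti_types[.nifti_types$code == dtcode, ]
  if (nrow(spec) != 1L) {
    stop("unsupported NIfTI datatype code: ", dtcode, call. = FALSE)
  }
  seek(con, 76)
  pd <- readBin(con, "numeric", 8, size = 4, endian = endian)
  seek(con, 108)
  vox_offset <- readBin(con, "numeric", 1, size = 4, endian = endian)
  slope <- readBin(con, "numeric", 1, size = 4, endian = endian)
  inter <- readBin(con, "numeric", 1, size = 4, endian = endian)
  seek(con, 344)
  magic <- rawToChar(readBin(con, "raw", 3))
  if (!magic %in% c("n+1", "ni1")) {
    stop("missing NIfTI magic string in ", path, call. = FALSE)
  }
  seek(con, vox_offset)
  n <- prod(dims)
  data <- readBin(con, spec$what, n, size = spec$size, signed = spec$signed,
                  endian = endian)
  data <- as.numeric(data)
  if (slope != 0 && !(slope == 1 && inter == 0)) {
    data <- data * slope + inter
  }
  list(data = array(data, dim = dims), pixdim = pd[2:4], tr = pd[5L],
       datatype = dtcode)
}

#' Combine left and right hemisphere labels into bilateral ROIs
#'
#' Labels carrying the same region name in the two hemispheres merge into
#' one bilateral ROI; labels without hemisphere annotation pass through as
#' their own ROI.
#'
#' @param label_table `data.frame` with columns `label` (integer), `region`
#'   (name) and `hemisphere` (`"L"`, `"R"` or `"none"`).
#' @return named list mapping bilateral ROI name to its integer labels.
#' @export
#' @examples
#' combine_hemispheres(data.frame(label = 1:2, region = "LG",
#'                                hemisphere = c("L", "R")))
combine_hemispheres <- function(label_table) {
  need <- c("label", "region", "hemisphere")
  miss <- setdiff(need, names(label_table))
  if (length(miss)) {
    stop("label table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(label_table$label)) {
    stop("duplicate integer labels in label table", call. = FALSE)
  }
  dup <- duplicated(label_table[, c("region", "hemisphere")])
  if (any(dup)) {
    stop("duplicate region name within one hemisphere: ",
         paste(unique(label_table$region[dup]), collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(label_table, label_table$region), function(g) {
    sort(g$label)
  })
  out[unique(label_table$region)]
}

required_event_columns <- c("onset", "duration", "method", "category",
                            "exemplar", "color")

check_events <- function(events, path = "<events>") {
  miss <- setdiff(required_event_columns, names(events))
  if (length(miss)) {
    stop("events table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  events$method <- match_method(events$method)
  events$category <- match_category(events$category)
  events
}

#' Write / read an events table
#'
#' Tab-separated, BIDS-events-like (columns `onset`, `duration`, `method`,
#' `category`, `exemplar`, `color`, plus any behavioral columns present).
#'
#' @param events events `data.frame`.
#' @param path file path.
#' @return `write_events`: `path` invisibly; `read_events`: the validated
#'   `data.frame` (method/category normalized).
#' @export
write_events <- function(events, path) {
  write.table(events, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read.delim(path, stringsAsFactors = FALSE)
  check_events(ev, path)
}

#' Write an `roi_dataset` to a directory
#'
#' Trial mode writes one tab-separated pattern table per ROI; timeseries
#' mode writes one 4-D NIfTI volume per run plus a 3-D integer label volume
#' and a label table. Both write per-run events tables (including behavior)
#' and a JSON manifest.
#'
#' @param dataset an `roi_dataset`.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  s <- dataset$subject
  pfx <- file.path(dir, sprintf("sub-%02d", as.integer(s)))
  runs <- sort(unique(dataset$events$run))
  events_files <- character(0)
  for (r in runs) {
    f <- sprintf("%s_run-%02d_events.tsv", pfx, r)
    write_events(dataset$events[dataset$events$run == r,
                                setdiff(names(dataset$events), "run")], f)
    events_files <- c(events_files, basename(f))
  }
  manifest <- list(subject = s, mode = dataset$mode,
                   tr_seconds = dataset$tr_seconds,
                   n_volumes = dataset$n_volumes,
                   runs = runs, rois = dataset$atlas$roi,
                   events = events_files)
  if (dataset$mode == "trial") {
    manifest$patterns <- setNames(vector("list", nrow(dataset$atlas)),
                                  dataset$atlas$roi)
    for (roi in dataset$atlas$roi) {
      f <- sprintf("%s_roi-%s_patterns.tsv", pfx, roi)
      mat <- dataset$patterns[[roi]]
      colnames(mat) <- paste0("V", seq_len(ncol(mat)))
      write.table(mat, f, sep = "\t", quote = FALSE, row.names = FALSE)
      manifest$patterns[[roi]] <- basename(f)
    }
  } else {
    nvox <- dataset$atlas$n_voxels
    labels <- rep(seq_along(nvox), nvox)
    label_file <- sprintf("%s_labels.nii", pfx)
    write_nifti(array(labels, dim = c(length(labels), 1L, 1L)), label_file,
                datatype = "int32")
    lt <- data.frame(label = seq_along(nvox), region = dataset$atlas$roi,
                     hemisphere = "none", stringsAsFactors = FALSE)
    lt_file <- sprintf("%s_label_table.tsv", pfx)
    write.table(lt, lt_file, sep = "\t", quote = FALSE, row.names = FALSE)
    bold_files <- character(0)
    for (r in runs) {
      vol <- do.call(cbind, lapply(dataset$series, function(x) x[[r]]))
      f <- sprintf("%s_run-%02d_bold.nii", pfx, r)
      write_nifti(array(t(vol), dim = c(ncol(vol), 1L, 1L, nrow(vol))), f,
                  tr = dataset$tr_seconds)
      bold_files <- c(bold_files, basename(f))
    }
    manifest$bold <- bold_files
    manifest$labels <- basename(label_file)
    manifest$label_table <- basename(lt_file)
  }
  mf <- sprintf("%s_dataset.json", pfx)
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
  invisible(mf)
}

#' Assemble an `roi_dataset` from NIfTI volumes, labels and events tables
#'
#' @param volume_paths one 4-D NIfTI per run, in run order.
#' @param label_path 3-D integer label volume on the same grid.
#' @param label_table_path tab-separated label table (`label`, `region`,
#'   `hemisphere`); hemisphere pairs are merged via
#'   [combine_hemispheres()].
#' @param events_paths one events TSV per run, in run order.
#' @param subject subject identifier.
#' @return an `roi_dataset` in timeseries mode.
#' @export
read_dataset <- function(volume_paths, label_path, label_table_path,
                         events_paths, subject = 1L) {
  if (length(volume_paths) != length(events_paths)) {
    stop("need one events table per volume", call. = FALSE)
  }
  lab <- read_nifti(label_path)
  lab_vec <- as.integer(round(as.vector(lab$data)))
  lt <- read.delim(label_table_path, stringsAsFactors = FALSE)
  roi_map <- combine_hemispheres(lt)
  present <- setdiff(unique(lab_vec), 0L)
  unknown <- setdiff(present, lt$label)
  if (length(unknown)) {
    stop("label volume contains label(s) absent from the label table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  vols <- lapply(volume_paths, read_nifti)
  for (i in seq_along(vols)) {
    if (!identical(dim(vols[[i]]$data)[1:3], dim(lab$data)[1:3])) {
      stop("volume grid of ", volume_paths[i],
           " does not match the label grid", call. = FALSE)
    }
  }
  tr <- vols[[1L]]$tr
  nv <- dim(vols[[1L]]$data)[4L]
  series <- lapply(roi_map, function(labels) {
    vox <- which(lab_vec %in% labels)
    lapply(vols, function(v) {
      flat <- matrix(v$data, nrow = prod(dim(v$data)[1:3]))
      t(flat[vox, , drop = FALSE])
    })
  })
  events <- do.call(rbind, lapply(seq_along(events_paths), function(r) {
    ev <- read_events(events_paths[r])
    cbind(run = r, trial = seq_len(nrow(ev)), ev)
  }))
  rownames(events) <- NULL
  # Built directly (not via roi_atlas): real parcellations may legitimately
  # contain single-voxel regions, which the simulation spec disallows.
  atlas <- data.frame(roi = names(roi_map), full_name = names(roi_map),
                      size_cm2 = NA_real_,
                      n_voxels = vapply(series, function(x) ncol(x[[1L]]),
                                        integer(1L)),
                      stringsAsFactors = FALSE)
  class(atlas) <- c("roi_atlas", "data.frame")
  structure(
    list(events = events, patterns = NULL, series = series, atlas = atlas,
         mode = "timeseries", tr_seconds = tr, n_volumes = nv,
         subject = subject),
    class = "roi_dataset"
  )
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir dataset directory.
#' @param subject subject identifier to load.
#' @return an `roi_dataset`.
#' @export
read_dataset_dir <- function(dir, subject = 1L) {
  pfx <- file.path(dir, sprintf("sub-%02d", as.integer(subject)))
  mf <- sprintf("%s_dataset.json", pfx)
  if (!file.exists(mf)) {
    stop("no dataset manifest found at ", mf, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  events_paths <- file.path(dir, manifest$events)
  if (manifest$mode == "timeseries") {
    ds <- read_dataset(file.path(dir, manifest$bold),
                       file.path(dir, manifest$labels),
                       file.path(dir, manifest$label_table),
                       events_paths, subject = subject)
    ds$n_volumes <- manifest$n_volumes
    return(ds)
  }
  events <- do.call(rbind, lapply(seq_along(events_paths), function(r) {
    ev <- read_events(events_paths[r])
    cbind(run = manifest$runs[r], trial = seq_len(nrow(ev)), ev)
  }))
  rownames(events) <- NULL
  patterns <- lapply(manifest$patterns, function(f) {
    as.matrix(read.delim(file.path(dir, f)))
  })
  names(patterns) <- names(manifest$patterns)
  patterns <- lapply(patterns, unname)
  atlas <- roi_atlas(roi_names = names(patterns),
                     n_voxels = vapply(patterns, ncol, integer(1L)))
  structure(
    list(events = events, patterns = patterns, series = NULL, atlas = atlas,
         mode = "trial", tr_seconds = manifest$tr_seconds,
         n_volumes = manifest$n_volumes, subject = subject),
    class = "roi_dataset"
  )
}

#' Write the group-analysis report
#'
#' Emits tab-separated group tables (a wide within-method table mirroring a
#' per-ROI mean/t/significance summary, the per-regime cross-method tables,
#' the paired contrasts and the subject-level results) plus a
#' machine-readable JSON report.
#'
#' @param analysis an `invisidec_analysis`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_analysis <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) {
    if (!is.null(x) && nrow(x)) {
      write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
  }
  # Wide within-method summary (the per-ROI mean d'/t/significance table).
  atlas <- analysis$axes$atlas
  wide <- data.frame(roi = atlas$roi, full_name = atlas$full_name,
                     stringsAsFactors = FALSE)
  for (m in .methods) {
    tb <- analysis$within[[paste0("within:", m)]]
    idx <- match(wide$roi, if (is.null(tb)) character() else tb$roi)
    wide[[paste0(m, "_mean_dprime")]] <- if (is.null(tb)) NA else
      tb$mean_dprime[idx]
    wide[[paste0(m, "_t")]] <- if (is.null(tb)) NA else tb$t[idx]
    wide[[paste0(m, "_significant")]] <- if (is.null(tb)) NA else
      tb$significant[idx]
  }
  wt(wide, "within_method_summary.tsv")
  for (nm in names(analysis$within)) {
    wt(analysis$within[[nm]], paste0(gsub("[:]", "_", nm), ".tsv"))
  }
  for (nm in names(analysis$cross)) {
    wt(analysis$cross[[nm]], paste0(gsub("[:-]", "_", nm), ".tsv"))
  }
  wt(analysis$contrasts, "paired_contrasts.tsv")
  wt(analysis$results, "subject_results.tsv")
  writeLines(analysis$gate, file.path(dir, "gate.txt"))
  jsonlite::write_json(
    list(config = analysis$config, gate = analysis$gate,
         within = analysis$within, cross = analysis$cross,
         contrasts = analysis$contrasts),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows", na = "null")
  invisible(dir)
}
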