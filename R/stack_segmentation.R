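#' Load an acquisition image series
#'
#' Lists the numbered images the camera wrote during a scan and orders
#' them by their acquisition sequence number. Segmentation never decodes
#' pixels: only the file name (for ordering) and the file size in bytes
#' (for sentinel detection) are used.
#'
#' @param x a directory path, or a data frame with columns `name` and
#'   `size` (bytes) for testing without files on disk.
#' @param extensions file extensions treated as images.
#' @param seq_pattern optional regular expression with one capture group
#'   extracting the sequence number from the base name; by default the
#'   last run of digits in the base name is used.
#' @return A data frame (class `image_series`) with columns `path`,
#'   `name`, `size`, `seq`, sorted by `seq`.
#' @export
load_series <- function(x, extensions = c("jpg", "jpeg", "png"),
                        seq_pattern = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (!dir.exists(x)) stop("directory not found: ", x, call. = FALSE)
    files <- list.files(x, full.names = TRUE)
    df <- data.frame(path = files, name = basename(files),
                     size = file.size(files))
  } else if (is.data.frame(x)) {
    df <- data.frame(path = if ("path" %in% names(x)) x$path else x$name,
                     name = x$name, size = x$size)
  } else stop("'x' must be a directory path or a data frame", call. = FALSE)

  ext <- tolower(tools::file_ext(df$name))
  df <- df[ext %in% tolower(extensions), , drop = FALSE]
  base <- tools::file_path_sans_ext(df$name)
  if (is.null(seq_pattern)) {
    df$seq <- vapply(base, function(b) {
      m <- regmatches(b, gregexpr("[0-9]+", b))[[1]]
      if (length(m) == 0L) NA_integer_ else as.integer(m[length(m)])
    }, integer(1), USE.NAMES = FALSE)
  } else {
    m <- regmatches(base, regexec(seq_pattern, base))
    df$seq <- vapply(m, function(g)
      if (length(g) >= 2L) as.integer(g[2]) else NA_integer_, integer(1))
  }
  df <- df[!is.na(df$seq), , drop = FALSE]
  if (nrow(df) == 0L)
    stop("no image files with a parseable sequence number", call. = FALSE)
  if (anyDuplicated(df$seq))
    stop("duplicate sequence numbers in series: ",
         paste(df$seq[duplicated(df$seq)], collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$size) | df$size <= 0))
    stop("images with missing or zero file size", call. = FALSE)
  df <- df[order(df$seq), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("image_series", "data.frame")
  df
}

# Candidate sentinels: records whose size falls below rel_threshold times
# the median size of their nearest non-candidate neighbours. Grown from
# the empty set to a fixpoint, so excluding detected sentinels from the
# neighbour pool only raises the reference median (the set is monotone in
# the threshold).
.sentinel_candidates <- function(sizes, expected_period, rel_threshold) {
  n <- length(sizes)
  cand <- rep(FALSE, n)
  repeat {
    changed <- FALSE
    pool <- which(!cand)
    for (i in pool) {
      nb <- pool[pool != i]
      if (length(nb) == 0L) next
      nb <- nb[order(abs(nb - i), nb)]
      nb <- nb[seq_len(min(expected_period, length(nb)))]
      if (sizes[i] < rel_threshold * stats::median(sizes[nb])) {
        cand[i] <- TRUE
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  which(cand)
}

# Lexicographic objective for a partition, every component minimized, in
# order: (1) stacks without a sentinel -- every detected sentinel that
# can legally terminate a stack should (a stack that lost a data frame
# must still claim its sentinel rather than swallow it as data to round
# out a neighbouring run); (2) minus the number of stacks matching the
# expected shape, exactly n_z data images plus sentinel (counting
# sentinel-less runs of n_z here would reward chopping the series into
# runs of n_z and ignoring the sentinels); (3) total stacks (no
# gratuitous splits); (4) squared deviation of data counts from n_z;
# (5) bytes of the records used as sentinels (a defocused sentinel
# compresses far smaller than any in-focus frame); (6) bytes at
# sentinel-less boundaries (split after the smallest file).
.obj_better <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0L && d[i[1]] < 0
}

# objective tuple of a complete partition (stacks as a data frame with
# from/to/sentinel), or NULL if infeasible (a stack longer than n_z, or
# a sentinel not strictly smaller than its stack's data records); used to
# check the dynamic alignment against exhaustive enumeration
.score_partition <- function(sizes, stacks, n_z) {
  n <- length(sizes)
  tot <- c(0, 0, 0, 0, 0, 0)
  for (k in seq_len(nrow(stacks))) {
    g <- stacks$to[k] - stacks$from[k] + 1L
    if (g < 1L || g > n_z) return(NULL)
    s <- stacks$sentinel[k]
    if (is.na(s)) {
      end <- stacks$to[k]
      tot <- tot + c(1, 0, 1, (g - n_z)^2, 0,
                     if (end < n) sizes[end] else 0)
    } else {
      if (sizes[s] >= min(sizes[stacks$from[k]:stacks$to[k]])) return(NULL)
      if (s < n && sizes[s] >= sizes[s + 1L]) return(NULL)
      tot <- tot + c(0, -as.numeric(g == n_z), 1, (g - n_z)^2, sizes[s], 0)
    }
  }
  tot
}

# Dynamic alignment of candidate sentinels with the expected stack
# periodicity. States are boundaries after record i; each stack consumes
# 1..n_z data records plus optionally one candidate record as its
# sentinel. A missing sentinel merges two stacks; the corresponding
# sentinel-less ("virtual") boundary inside the series splits them again,
# by construction at most n_z records apart.
.reconcile_sentinels <- function(sizes, candidates, n_z) {
  n <- length(sizes)
  is_cand <- rep(FALSE, n)
  is_cand[candidates] <- TRUE
  NEG <- c(Inf, Inf, Inf, Inf, Inf, Inf)
  best <- matrix(rep(NEG, n + 1L), nrow = n + 1L, byrow = TRUE)
  best[1L, ] <- c(0, 0, 0, 0, 0, 0)
  prev <- rep(NA_integer_, n + 1L)       # previous boundary (0-based + 1)
  sent <- rep(NA_integer_, n + 1L)       # sentinel record ending the stack
  for (i0 in 0:(n - 1L)) {
    bi <- best[i0 + 1L, ]
    if (!is.finite(bi[3])) next
    min_data <- Inf
    for (g in 1:n_z) {
      j <- i0 + g
      if (j > n) break
      min_data <- min(min_data, sizes[j])
      # end the stack without a sentinel (series end or missing sentinel)
      cj <- bi + c(1, 0, 1, (g - n_z)^2, 0, if (j < n) sizes[j] else 0)
      if (.obj_better(cj, best[j + 1L, ])) {
        best[j + 1L, ] <- cj
        prev[j + 1L] <- i0 + 1L
        sent[j + 1L] <- NA_integer_
      }
      # end the stack with a candidate sentinel at j + 1; the sentinel's
      # defining signature is that it compresses smaller than every
      # in-focus frame of its own stack and than the frame that follows
      # it (the next well's first image)
      k <- j + 1L
      if (k <= n && is_cand[k] && sizes[k] < min_data &&
          (k == n || sizes[k] < sizes[k + 1L])) {
        ck <- bi + c(0, -as.numeric(g == n_z), 1, (g - n_z)^2, sizes[k], 0)
        if (.obj_better(ck, best[k + 1L, ])) {
          best[k + 1L, ] <- ck
          prev[k + 1L] <- i0 + 1L
          sent[k + 1L] <- k
        }
      }
    }
  }
  if (!is.finite(best[n + 1L, 3]))
    stop("candidate sentinel spacing is incompatible with n_z = ", n_z,
         "; candidates at indices: ",
         paste(candidates, collapse = ", "), call. = FALSE)
  # trace back
  stacks <- list()
  at <- n + 1L
  while (at > 1L) {
    p <- prev[at]
    s <- sent[at]
    last_data <- if (is.na(s)) at - 1L else s - 1L
    stacks[[length(stacks) + 1L]] <-
      list(from = p, to = last_data, sentinel = s)  # from is 1-based start
    at <- p
  }
  rev(stacks)
}

#' Detect sentinel images and partition a series into z-stacks
#'
#' Each well's series ends with a deliberately out-of-focus image whose
#' JPEG size is markedly smaller than the in-focus frames flanking it.
#' Candidates are records whose size falls below `rel_threshold` times the
#' median size of their nearest non-sentinel neighbours; the candidate set
#' is then reconciled with the expected stack structure (1 to `n_z` data
#' images between boundaries) by dynamic alignment that maximizes the
#' number of stacks with exactly `n_z` data images. This recovers the
#' partition even when occasional images are missing: a missing data
#' image shortens its stack, and a missing sentinel merges two stacks
#' which the alignment splits again at the size minimum.
#'
#' @param records an `image_series` from [load_series()], or a numeric
#'   vector of file sizes.
#' @param expected_period expected records per well, i.e. `n_z + 1` with
#'   the sentinel enabled.
#' @param rel_threshold fraction of the neighbour median below which a
#'   record is a sentinel candidate.
#' @return An object of class `sentinel_detection`: list with `sentinels`
#'   (indices into the ordered series), `candidates`, and `stacks` (a data
#'   frame with 1-based `from`, `to` data-record range and `sentinel`
#'   index, `NA` if that stack's sentinel is missing).
#' @export
detect_sentinels <- function(records, expected_period,
                             rel_threshold = 0.75) {
  sizes <- if (is.data.frame(records)) records$size else as.numeric(records)
  if (length(sizes) < 2L)
    stop("need at least 2 records to detect sentinels", call. = FALSE)
  if (!is.numeric(expected_period) || expected_period < 2L)
    stop("'expected_period' must be n_z + 1 >= 2", call. = FALSE)
  n_z <- as.integer(expected_period) - 1L
  candidates <- .sentinel_candidates(sizes, as.integer(expected_period),
                                     rel_threshold)
  if (length(candidates) == 0L)
    stop("no sentinel candidates found; the acquisition may have been ",
         "run without sentinel images, or rel_threshold (",
         rel_threshold, ") is too low", call. = FALSE)
  stacks <- .reconcile_sentinels(sizes, candidates, n_z)
  st <- data.frame(
    from = vapply(stacks, `[[`, integer(1), "from"),
    to = vapply(stacks, `[[`, integer(1), "to"),
    sentinel = vapply(stacks, function(s)
      if (is.null(s$sentinel) || is.na(s$sentinel)) NA_integer_
      else as.integer(s$sentinel), integer(1))
  )
  structure(list(sentinels = st$sentinel[!is.na(st$sentinel)],
                 candidates = candidates, stacks = st, n_z = n_z),
            class = "sentinel_detection")
}

#' @export
print.sentinel_detection <- function(x, ...) {
  cat(sprintf(
    "<sentinel_detection> %d stacks (%d with sentinel), n_z = %d\n",
    nrow(x$stacks), sum(!is.na(x$stacks$sentinel)), x$n_z))
  invisible(x)
}

#' Assign detected stacks to wells
#'
#' Labels the k-th detected stack with the k-th well of the scan order
#' the plate was acquired in (the inverse of [well_order()]). Fewer
#' stacks than wells sets the `mismatch` flag and labels only the leading
#' wells; more stacks than wells is an error.
#'
#' @param detection a `sentinel_detection` from [detect_sentinels()].
#' @param records the `image_series` the detection was computed on.
#' @param spec a [plate_spec()].
#' @param order scan order used during acquisition.
#' @return A `series_manifest`: list with one element per stack (`well`,
#'   `data` record table, `sentinel` record or `NULL`, `complete` flag)
#'   plus metadata.
#' @export
assign_wells <- function(detection, records, spec,
                         order = c("row-serpentine", "row-major")) {
  stopifnot(inherits(detection, "sentinel_detection"),
            is.data.frame(records), inherits(spec, "plate_spec"))
  order <- match.arg(order)
  wo <- well_order(spec, order)
  st <- detection$stacks
  if (nrow(st) > nrow(wo))
    stop(sprintf("found %d stacks but the %s plate has only %d wells",
                 nrow(st), spec$name, nrow(wo)), call. = FALSE)
  stacks <- vector("list", nrow(st))
  for (k in seq_len(nrow(st))) {
    data_rec <- records[st$from[k]:st$to[k], , drop = FALSE]
    sent_rec <- if (is.na(st$sentinel[k])) NULL
                else records[st$sentinel[k], , drop = FALSE]
    stacks[[k]] <- list(well = wo$well[k], data = data_rec,
                        sentinel = sent_rec,
                        complete = nrow(data_rec) == detection$n_z)
  }
  structure(list(stacks = stacks, plate = spec$name, n_z = detection$n_z,
                 order = order, mismatch = nrow(st) != nrow(wo)),
            class = "series_manifest")
}

#' Segment an acquisition directory into per-well z-stacks
#'
#' Convenience pipeline: [load_series()], [detect_sentinels()],
#' [assign_wells()].
#'
#' @param dir directory of numbered images (or an `image_series`).
#' @param spec a [plate_spec()] or builtin plate name.
#' @param n_z data images per well.
#' @param order scan order used during acquisition.
#' @param rel_threshold sentinel size threshold, see [detect_sentinels()].
#' @param sentinel whether the acquisition included sentinel images
#'   (currently required for segmentation).
#' @return A `series_manifest`.
#' @export
#' @examples
#' \dontrun{
#' m <- segment_series("scan_output/", "96")
#' write_manifest(m, "manifest.json")
#' }
segment_series <- function(dir, spec, n_z = 5L,
                           order = c("row-serpentine", "row-major"),
                           rel_threshold = 0.75, sentinel = TRUE) {
  if (!isTRUE(sentinel))
    stop("segmentation requires sentinel images; acquisitions without ",
         "them cannot be partitioned reliably", call. = FALSE)
  if (is.character(spec)) spec <- builtin_plate(spec)
  order <- match.arg(order)
  records <- if (inherits(dir, "image_series")) dir else load_series(dir)
  det <- detect_sentinels(records, expected_period = n_z + 1L,
                          rel_threshold = rel_threshold)
  assign_wells(det, records, spec, order)
}

#' @export
print.series_manifest <- function(x, ...) {
  n_complete <- sum(vapply(x$stacks, `[[`, logical(1), "complete"))
  cat(sprintf(
    "<series_manifest> plate %s: %d stacks (%d complete with %d images)%s\n",
    x$plate, length(x$stacks), n_complete, x$n_z,
    if (x$mismatch) " [stack/well count mismatch]" else ""))
  invisible(x)
}

#' Flatten a manifest to a table
#'
#' @param x a `series_manifest`.
#' @param ... unused.
#' @return Data frame with columns `well`, `z_index` (1-based, top of
#'   stack first; 0 marks the sentinel), `filename`.
#' @export
as.data.frame.series_manifest <- function(x, ...) {
  rows <- lapply(x$stacks, function(s) {
    d <- data.frame(well = s$well, z_index = seq_len(nrow(s$data)),
                    filename = s$data$name)
    if (!is.null(s$sentinel))
      d <- rbind(d, data.frame(well = s$well, z_index = 0L,
                               filename = s$sentinel$name))
    d
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a manifest to JSON (and optionally CSV)
#'
#' @param manifest a `series_manifest`.
#' @param path output JSON path.
#' @param csv optional path for the flat CSV table
#'   (see [as.data.frame.series_manifest()]).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path, csv = NULL) {
  stopifnot(inherits(manifest, "series_manifest"))
  obj <- list(
    plate = manifest$plate, n_z = manifest$n_z, order = manifest$order,
    mismatch = manifest$mismatch,
    stacks = lapply(manifest$stacks, function(s) list(
      well = s$well,
      files = s$data$name,
      paths = s$data$path,
      sentinel = if (is.null(s$sentinel)) NULL else s$sentinel$name,
      sentinel_path = if (is.null(s$sentinel)) NULL else s$sentinel$path,
      complete = s$complete
    ))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null",
                       pretty = TRUE)
  if (!is.null(csv))
    utils::write.csv(as.data.frame(manifest), csv, row.names = FALSE)
  invisible(path)
}

#' Read a manifest written by [write_manifest()]
#'
#' @param path JSON path.
#' @return A `series_manifest` (record tables carry `name`, `path`;
#'   sizes/seq are not round-tripped).
#' @export
read_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  stacks <- lapply(obj$stacks, function(s) list(
    well = s$well,
    data = data.frame(path = unlist(s$paths), name = unlist(s$files)),
    sentinel = if (is.null(s$sentinel)) NULL
               else data.frame(path = s$sentinel_path, name = s$sentinel),
    complete = isTRUE(s$complete)
  ))
  structure(list(stacks = stacks, plate = obj$plate, n_z = obj$n_z,
                 order = obj$order, mismatch = isTRUE(obj$mismatch)),
            class = "series_manifest")
}
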