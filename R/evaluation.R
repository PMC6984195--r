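#' Case annotation: CALC point and couch shift
#'
#' The clinically documented inputs of the TRE evaluation: the dose
#' calculation point (CALC) in planning-CT space, and the 3D translational
#' couch shift (left-right, anterior-posterior, superior-inferior, mm)
#' applied to reposition the patient. The stored vector is the applied couch
#' correction; the CBCT-space CALC is `calc - couch_shift` ("applied with
#' the inverse couch shift"). Record-system conventions vary, so the sign
#' can be flipped per data source with `shift_sign`.
#'
#' @param calc numeric(3), CALC coordinates in mm (planning-CT space).
#' @param couch_shift numeric(3), couch shift in mm.
#' @param case_id optional label.
#' @param shift_sign `+1` or `-1` applied to `couch_shift` on construction.
#' @return A `vs_annotation` object.
#' @export
case_annotation <- function(calc, couch_shift = c(0, 0, 0), case_id = "case",
                            shift_sign = 1) {
  calc <- as.numeric(calc); couch_shift <- shift_sign * as.numeric(couch_shift)
  if (length(calc) != 3L || any(!is.finite(calc)))
    stop("`calc` must be 3 finite mm coordinates")
  if (length(couch_shift) != 3L || any(!is.finite(couch_shift)))
    stop("`couch_shift` must be 3 finite mm components")
  if (sqrt(sum(couch_shift^2)) > 50)
    warning(sprintf("couch shift |%.1f| mm exceeds the 50 mm plausibility guard",
                    sqrt(sum(couch_shift^2))))
  structure(list(calc = calc, couch_shift = couch_shift,
                 case_id = as.character(case_id)),
            class = "vs_annotation")
}

#' Target registration error at the CALC point
#'
#' The CALC documented in the planning CT, taken back to the prepositioned
#' CBCT frame by the inverse couch shift, should be mapped by a correct
#' registration onto the CALC again: `p_cbct = calc - couch_shift`,
#' `q_ct = transform_point(field, p_cbct)`, `TRE = |q_ct - calc|` in mm.
#'
#' @param ann a [case_annotation()].
#' @param field the forward (reference CBCT to floating CT)
#'   [deformation_field()].
#' @return TRE in mm.
#' @export
compute_tre <- function(ann, field) {
  stopifnot(inherits(ann, "vs_annotation"))
  p_cbct <- ann$calc - ann$couch_shift
  q_ct <- transform_point(field, p_cbct)
  sqrt(sum((q_ct - ann$calc)^2))
}

#' Self-TRE (STRE): forward/reverse registration consistency
#'
#' For each of `n_points` points `p` sampled uniformly in a ball inside the
#' reference (CBCT) space: `t = transform_point(forward, p)`,
#' `p' = transform_point(reverse, t)`, `STRE_p = |p - p'|`. Zero for exactly
#' inverse field pairs; the mean over points is the automatic QA statistic.
#' Points falling outside either field's extent are discarded; fewer than 10
#' valid points is an error.
#'
#' @param forward,reverse [deformation_field()]s from the forward (CBCT to
#'   CT) and reverse (CT to CBCT) registrations.
#' @param region_center numeric(3) mm, center of the target region
#'   (typically the isocenter or CALC).
#' @param region_radius ball radius in mm (default 30).
#' @param n_points number of sampled points (default 1000).
#' @param seed integer seed for the point sample.
#' @return Mean STRE in mm, with attributes `n_valid` and `stre` (per-point
#'   values).
#' @export
compute_stre <- function(forward, reverse, region_center, region_radius = 30,
                         n_points = 1000L, seed = 1L) {
  stopifnot(inherits(forward, "vs_field"), inherits(reverse, "vs_field"))
  pts <- with_seed(seed, sample_ball(n_points, region_center, region_radius))
  inside <- function(field, p)
    apply(sweep(sweep(p, 2, field$origin), 2, field$spacing, "/"), 1,
          function(v) all(v >= 0 & v <= field$dims - 1))
  ok <- inside(forward, pts)
  stre <- rep(NA_real_, n_points)
  if (any(ok)) {
    t_pts <- transform_point(forward, pts[ok, , drop = FALSE])
    ok2 <- inside(reverse, t_pts)
    idx <- which(ok)[ok2]
    if (length(idx) > 0L) {
      p2 <- transform_point(reverse, t_pts[ok2, , drop = FALSE])
      stre[idx] <- sqrt(rowSums((pts[idx, , drop = FALSE] - p2)^2))
    }
  }
  valid <- which(!is.na(stre))
  if (length(valid) < 10L)
    stop(sprintf("compute_stre: only %d of %d sampled points valid in both fields",
                 length(valid), n_points))
  out <- mean(stre[valid])
  attr(out, "n_valid") <- length(valid)
  attr(out, "stre") <- stre[valid]
  out
}

sample_ball <- function(n, center, radius) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    m <- matrix(stats::runif(3 * 2 * (n - got), -1, 1), ncol = 3)
    keep <- rowSums(m^2) <= 1
    m <- m[keep, , drop = FALSE]
    take <- min(nrow(m), n - got)
    if (take > 0L)
      pts[got + seq_len(take), ] <- m[seq_len(take), , drop = FALSE]
    got <- got + take
  }
  sweep(pts * radius, 2, as.numeric(center), "+")
}

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Registration QA decision from the STRE rule
#'
#' Pass iff the mean STRE does not exceed the voxel size (read as the
#' maximum spacing component, typically the slice thickness); on failure the
#' prescribed action is to rerun the registration with the next parameter
#' set from a configured fallback list. Equality passes (documented
#' boundary convention).
#'
#' @param mean_stre mean STRE in mm.
#' @param voxel_size voxel size in mm (max spacing component).
#' @param n_points number of points behind `mean_stre` (bookkeeping).
#' @return A `vs_qa_report`: `mean_stre`, `n_points`, `voxel_size`,
#'   `passed`, `action` (`"none"` or `"rerun_with_new_parameters"`).
#' @export
qa_check <- function(mean_stre, voxel_size, n_points = NA_integer_) {
  if (!is.finite(mean_stre) || mean_stre < 0 || !is.finite(voxel_size) ||
      voxel_size <= 0)
    stop("qa_check: inputs must be positive")
  passed <- mean_stre <= voxel_size
  structure(list(mean_stre = as.numeric(mean_stre),
                 n_points = as.integer(n_points),
                 voxel_size = as.numeric(voxel_size), passed = passed,
                 action = if (passed) "none" else "rerun_with_new_parameters"),
            class = "vs_qa_report")
}

#' @export
print.vs_qa_report <- function(x, ...) {
  cat(sprintf("<vs_qa_report> mean STRE %.3f mm vs voxel %.2f mm: %s%s\n",
              x$mean_stre, x$voxel_size, if (x$passed) "PASS" else "FAIL",
              if (x$passed) "" else " (rerun with new parameters)"))
  invisible(x)
}

#' Voxel size used by the QA rule
#' @param spacing numeric(3) spacing in mm, or a [vs_volume()].
#' @return Max spacing component in mm.
#' @export
qa_voxel_size <- function(spacing) {
  if (is_vs_volume(spacing)) spacing <- spacing$spacing
  max(spacing)
}

#' Read / write case annotation sidecar files
#'
#' Delimited text, one row per case: `case, calc_x, calc_y, calc_z,
#' shift_x, shift_y, shift_z`.
#'
#' @param path a TSV/CSV path (separator inferred from the extension).
#' @param anns list of [case_annotation()]s.
#' @return `read_annotations` returns a named list of annotations.
#' @export
read_annotations <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("case", "calc_x", "calc_y", "calc_z", "shift_x", "shift_y", "shift_z")
  if (!all(need %in% names(df)))
    stop(sprintf("annotation file '%s': missing columns %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")))
  out <- lapply(seq_len(nrow(df)), function(i)
    case_annotation(c(df$calc_x[i], df$calc_y[i], df$calc_z[i]),
                    c(df$shift_x[i], df$shift_y[i], df$shift_z[i]),
                    case_id = df$case[i]))
  stats::setNames(out, df$case)
}

#' @rdname read_annotations
#' @export
write_annotations <- function(anns, path) {
  df <- do.call(rbind, lapply(anns, function(a)
    data.frame(case = a$case_id, calc_x = a$calc[1], calc_y = a$calc[2],
               calc_z = a$calc[3], shift_x = a$couch_shift[1],
               shift_y = a$couch_shift[2], shift_z = a$couch_shift[3])))
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-factor-at-a-time parameter sweep
#'
#' Runs the full registration + TRE evaluation for every (pair, parameter
#' set) combination through the batch executor and reports one row per
#' combination plus a per-set summary (mean TRE, wall time). Mirrors the
#' parameter-optimization design in which set 1 holds defaults and the
#' remaining sets vary one parameter each; at paper scale that is
#' 132 pairs x 12 sets.
#'
#' @param pairs list of `list(ref =, flt =, ann =)` entries
#'   ([vs_volume()]s or file paths, plus a [case_annotation()]).
#' @param sets list of [parameter_set()]s (names become set labels).
#' @param n_workers worker count for the batch executor.
#' @param compute_stre also run the reverse registration and STRE QA per job
#'   (slower; default `FALSE` for sweeps).
#' @param seed base seed; each job derives its own from it.
#' @return A data.frame with columns `case, set, tre_mm, ssim, mean_stre,
#'   qa_pass, seconds, status`, one row per (pair, set); per-set summary in
#'   `attr(, "per_set")`.
#' @export
parameter_sweep <- function(pairs, sets, n_workers = 1L, compute_stre = FALSE,
                            seed = 1L) {
  if (length(pairs) < 1L || length(sets) < 1L)
    stop("parameter_sweep: need at least one pair and one set")
  set_names <- names(sets)
  if (is.null(set_names))
    set_names <- vapply(seq_along(sets), function(i)
      if (!is.null(sets[[i]]$name) && nzchar(sets[[i]]$name)) sets[[i]]$name
      else sprintf("set%02d", i), character(1))
  jobs <- list()
  for (si in seq_along(sets))
    for (pi in seq_along(pairs)) {
      p <- pairs[[pi]]
      cid <- if (!is.null(p$ann)) p$ann$case_id else sprintf("pair%d", pi)
      jobs[[length(jobs) + 1L]] <- job_message(
        id = sprintf("%s:%s", cid, set_names[si]),
        ref = p$ref, flt = p$flt, ann = p$ann, params = sets[[si]],
        meta = list(case = cid, set = set_names[si],
                    seed = job_seed(seed, length(jobs) + 1L)))
    }
  q <- job_queue()
  enqueue(q, jobs)
  done <- run_queue(q, executor = make_executor(compute_stre = compute_stre),
                    n_workers = n_workers, max_retries = 0L)
  rows <- lapply(done, function(j) {
    m <- j$result
    data.frame(case = j$meta$case, set = j$meta$set,
               tre_mm = if (is.null(m$tre_mm)) NA_real_ else m$tre_mm,
               ssim = if (is.null(m$ssim)) NA_real_ else m$ssim,
               mean_stre = if (is.null(m$mean_stre)) NA_real_ else m$mean_stre,
               qa_pass = if (is.null(m$qa_pass)) NA else m$qa_pass,
               seconds = if (is.null(m$seconds)) NA_real_ else m$seconds,
               status = j$status, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res <- res[order(match(res$set, set_names), res$case), , drop = FALSE]
  rownames(res) <- NULL
  ok <- res$status == "done"
  per_set <- do.call(rbind, lapply(set_names, function(s) {
    sel <- ok & res$set == s
    data.frame(set = s, n_done = sum(sel), n_failed = sum(!ok & res$set == s),
               mean_tre = if (any(sel)) mean(res$tre_mm[sel]) else NA_real_,
               total_seconds = sum(res$seconds[res$set == s], na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  attr(res, "per_set") <- per_set
  res
}
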