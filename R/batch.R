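# Queue/worker batch execution mirroring the decoupled cloud design:
# a client populates a queue with job descriptions; each worker repeatedly
# pops a message and executes it until the queue is empty. Locally the
# (storage, queue, compute-node) trio maps to (file paths / an in-process
# persistent queue / a worker pool); the message schema keeps the payload
# fields (inputs, parameters, outputs) so a cloud adapter can be added
# without touching the executor.

#' Create a batch job message
#'
#' @param id unique job identifier within a batch.
#' @param ref,flt reference/floating inputs: [vs_volume()]s or file paths.
#' @param ann optional [case_annotation()].
#' @param params a [parameter_set()].
#' @param out optional output descriptor (e.g. a directory for field/warp).
#' @param meta free-form list (case/set labels, per-job seed).
#' @return A `vs_job` list with `status = "queued"`, `attempt = 1`.
#' @export
job_message <- function(id, ref, flt, ann = NULL, params = parameter_set(),
                        out = NULL, meta = list()) {
  structure(list(id = as.character(id), ref = ref, flt = flt, ann = ann,
                 params = params, out = out, meta = meta,
                 attempt = 1L, status = "queued", result = NULL, log = NULL),
            class = "vs_job")
}

#' In-process job queue
#'
#' FIFO queue with unique-id admission. [enqueue()] preserves order and
#' rejects (with a report) jobs whose id duplicates one already admitted;
#' [pop_job()] removes and returns the head, or `NULL` when empty.
#'
#' @return `job_queue()` returns an empty `vs_queue`.
#' @export
job_queue <- function() {
  q <- new.env(parent = emptyenv())
  q$items <- list()
  q$seen_ids <- character(0)
  class(q) <- "vs_queue"
  q
}

#' @rdname job_queue
#' @param queue a `vs_queue`.
#' @param jobs list of [job_message()]s (or a single one).
#' @return `enqueue` returns the number admitted, with attribute `rejected`
#'   naming rejected duplicate ids.
#' @export
enqueue <- function(queue, jobs) {
  stopifnot(inherits(queue, "vs_queue"))
  if (inherits(jobs, "vs_job")) jobs <- list(jobs)
  rejected <- character(0)
  n <- 0L
  for (j in jobs) {
    if (j$id %in% queue$seen_ids) {
      rejected <- c(rejected, j$id)
      next
    }
    queue$items[[length(queue$items) + 1L]] <- j
    queue$seen_ids <- c(queue$seen_ids, j$id)
    n <- n + 1L
  }
  if (length(rejected) > 0L)
    warning(sprintf("enqueue: rejected duplicate job id(s): %s",
                    paste(rejected, collapse = ", ")))
  structure(n, rejected = rejected)
}

#' @rdname job_queue
#' @export
pop_job <- function(queue) {
  stopifnot(inherits(queue, "vs_queue"))
  if (length(queue$items) == 0L) return(NULL)
  j <- queue$items[[1L]]
  queue$items[[1L]] <- NULL
  j
}

#' @rdname job_queue
#' @export
queue_length <- function(queue) length(queue$items)

job_seed <- function(base, i) (as.integer(base) * 1009L + i * 7919L) %% 2000000011L

# Re-enqueue a QA-failed job with the next fallback parameter set.
retry_job <- function(job, fallback_sets) {
  idx <- job$attempt  # attempt 1 failed -> fallback_sets[[1]], etc.
  if (idx > length(fallback_sets)) return(NULL)
  nj <- job
  nj$params <- fallback_sets[[idx]]
  nj$attempt <- job$attempt + 1L
  nj$id <- sprintf("%s#retry%d", sub("#retry\\d+$", "", job$id), nj$attempt)
  nj$status <- "queued"
  nj$result <- NULL
  nj
}

#' Run a queue to completion with a worker pool
#'
#' In every round up to `n_workers` messages are popped and executed
#' (forked workers via the parallel package when `n_workers > 1`); the loop
#' terminates when the queue is empty. Each popped job ends `done` or
#' `failed`; an executor exception marks the job `failed` with the captured
#' message and the loop continues. A job whose QA check fails is recorded
#' (`qa_rerun`) and re-enqueued once per remaining retry with the next
#' fallback parameter set, so no job executes more than `1 + max_retries`
#' times. Results are independent of `n_workers` because each job carries
#' its own seed and jobs do not interact.
#'
#' @param queue a [job_queue()] already populated via [enqueue()].
#' @param executor `function(job) -> list` of metrics; a `qa_pass = FALSE`
#'   entry triggers the retry path.
#' @param n_workers parallel worker count (default 1).
#' @param max_retries retry budget on QA failure (default 2).
#' @param fallback_sets list of [parameter_set()]s used by retries, in order.
#' @return List of terminal job messages (status `done` or `failed`), plus
#'   any intermediate `qa_rerun` records, in completion order.
#' @export
run_queue <- function(queue, executor, n_workers = 1L, max_retries = 2L,
                      fallback_sets = list()) {
  stopifnot(inherits(queue, "vs_queue"))
  completed <- list()
  use_fork <- n_workers > 1L && requireNamespace("parallel", quietly = TRUE) &&
    .Platform$OS.type == "unix"
  while (queue_length(queue) > 0L) {
    batch <- list()
    while (length(batch) < n_workers && queue_length(queue) > 0L)
      batch[[length(batch) + 1L]] <- pop_job(queue)
    runner <- function(job) {
      tryCatch(list(ok = TRUE, result = executor(job)),
               error = function(e) list(ok = FALSE,
                                        log = conditionMessage(e)))
    }
    outs <- if (use_fork)
      parallel::mclapply(batch, runner, mc.cores = n_workers)
    else lapply(batch, runner)
    for (i in seq_along(batch)) {
      job <- batch[[i]]
      o <- outs[[i]]
      if (inherits(o, "try-error") || !isTRUE(o$ok)) {
        job$status <- "failed"
        job$log <- if (!is.null(o$log)) o$log else as.character(o)
        completed[[length(completed) + 1L]] <- job
        next
      }
      job$result <- o$result
      qa_failed <- isFALSE(o$result$qa_pass)
      nj <- if (qa_failed && job$attempt <= max_retries)
        retry_job(job, fallback_sets) else NULL
      if (!is.null(nj)) {
        job$status <- "qa_rerun"
        completed[[length(completed) + 1L]] <- job
        enqueue(queue, nj)
      } else {
        job$status <- "done"
        completed[[length(completed) + 1L]] <- job
      }
    }
  }
  completed
}

#' Single-worker queue loop
#'
#' One worker popping and executing messages until the queue is empty --
#' the per-node behavior of the batch design. Equivalent to
#' [run_queue()] with `n_workers = 1`.
#'
#' @inheritParams run_queue
#' @return See [run_queue()].
#' @export
worker_loop <- function(queue, executor, max_retries = 2L,
                        fallback_sets = list()) {
  run_queue(queue, executor, n_workers = 1L, max_retries = max_retries,
            fallback_sets = fallback_sets)
}

#' Standard registration executor
#'
#' Builds the `function(job)` run by the workers: load inputs if given as
#' paths, preprocess, register hierarchically, interpolate the dense field,
#' warp, and evaluate (TRE if annotated, SSIM before/after, minimum
#' Jacobian; optionally the reverse registration + STRE QA check).
#'
#' @param compute_stre run the reverse registration and the STRE QA rule.
#' @param stre_points,stre_radius STRE sampling controls.
#' @param keep_field include the dense field in the result (memory-heavy).
#' @return `function(job) -> list` of metrics.
#' @export
make_executor <- function(compute_stre = TRUE, stre_points = 1000L,
                          stre_radius = 30, keep_field = FALSE) {
  force(compute_stre); force(stre_points); force(stre_radius)
  function(job) {
    t0 <- proc.time()[["elapsed"]]
    ref <- if (is_vs_volume(job$ref)) job$ref else read_volume(job$ref)
    flt <- if (is_vs_volume(job$flt)) job$flt else read_volume(job$flt)
    params <- job$params
    pre_ref <- preprocess_volume(ref, params$ref_window, params$smooth)
    pre_flt <- preprocess_volume(flt, params$flt_window, params$smooth)
    hier <- hierarchical_register(ref, flt, params)
    field <- interpolate_field(hier)
    warped <- warp(pre_flt, field)
    mask <- fov_mask(pre_ref)
    res <- list(
      tre_mm = if (!is.null(job$ann)) compute_tre(job$ann, field) else NA_real_,
      ssim_before = ssim3d(pre_flt, pre_ref, mask),
      ssim = ssim3d(warped, pre_ref, mask),
      jacobian_min = jacobian_min(field),
      n_leaves = hier$n_leaves, n_unrefined = hier$n_unrefined)
    if (compute_stre) {
      rparams <- params
      rparams$ref_window <- params$flt_window
      rparams$flt_window <- params$ref_window
      rparams$global_ref_window <- params$global_flt_window
      rparams$global_flt_window <- params$global_ref_window
      rhier <- hierarchical_register(flt, ref, rparams)
      rfield <- interpolate_field(rhier)
      center <- if (!is.null(job$ann)) job$ann$calc - job$ann$couch_shift
      else voxel_to_physical(ref, (ref$dims - 1) / 2)
      seed <- if (!is.null(job$meta$seed)) job$meta$seed else 1L
      stre <- compute_stre(field, rfield, center, stre_radius,
                           stre_points, seed)
      qa <- qa_check(as.numeric(stre), qa_voxel_size(ref),
                     attr(stre, "n_valid"))
      res$mean_stre <- as.numeric(stre)
      res$qa_pass <- qa$passed
      res$qa_action <- qa$action
    }
    res$seconds <- proc.time()[["elapsed"]] - t0
    if (keep_field) res$field <- field
    res
  }
}

#' Run a batch from a manifest file
#'
#' The manifest is delimited text (TSV, or CSV by extension) with header
#' `case, ref, flt, calc_x, calc_y, calc_z, shift_x, shift_y, shift_z`
#' and optionally `set` naming an entry of `sets`. Each row becomes one job.
#' A completed-jobs ledger file, when given, makes reruns idempotent: rows
#' whose job id already appears in the ledger are not re-executed, and every
#' finished job is appended to the ledger as it completes.
#'
#' @param manifest path to the manifest file.
#' @param n_workers worker count.
#' @param sets named list of [parameter_set()]s (first is the default).
#' @param compute_stre run reverse registration + STRE QA per job.
#' @param max_retries QA-failure retry budget.
#' @param ledger optional path to the completed-jobs ledger (TSV).
#' @param seed base seed; per-job seeds derive from it and the row number.
#' @param executor optional `function(job)` overriding the default
#'   [make_executor()] result (used for instrumented or rigged executors in
#'   tests).
#' @return Summary data.frame, one row per terminal job record: `id, case,
#'   set, attempt, status, tre_mm, ssim_before, ssim, mean_stre, qa_pass,
#'   jacobian_min, seconds`.
#' @export
run_batch <- function(manifest, n_workers = 1L, sets = list(default = parameter_set()),
                      compute_stre = TRUE, max_retries = 2L, ledger = NULL,
                      seed = 1L, executor = NULL) {
  sep <- if (grepl("\\.csv$", manifest)) "," else "\t"
  df <- tryCatch(utils::read.table(manifest, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE),
                 error = function(e) stop(sprintf("manifest '%s': %s",
                                                  manifest, conditionMessage(e))))
  need <- c("case", "ref", "flt")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop(sprintf("manifest '%s': missing column(s) %s", manifest,
                 paste(miss, collapse = ", ")))
  has_ann <- all(c("calc_x", "calc_y", "calc_z") %in% names(df))
  bad <- which(is.na(df$ref) | !nzchar(df$ref) | is.na(df$flt) | !nzchar(df$flt))
  if (length(bad) > 0L)
    stop(sprintf("manifest '%s': empty ref/flt path at line %s", manifest,
                 paste(bad + 1L, collapse = ", ")))
  done_ids <- character(0)
  prior <- NULL
  if (!is.null(ledger) && file.exists(ledger)) {
    prior <- utils::read.table(ledger, header = TRUE, sep = "\t",
                               stringsAsFactors = FALSE)
    done_ids <- prior$id[prior$status %in% c("done", "failed")]
  }
  base_dir <- dirname(manifest)
  resolve <- function(p) if (file.exists(p) || dir.exists(p)) p
  else file.path(base_dir, p)
  jobs <- list()
  for (i in seq_len(nrow(df))) {
    set_name <- if ("set" %in% names(df) && nzchar(df$set[i])) df$set[i]
    else names(sets)[1]
    if (!set_name %in% names(sets))
      stop(sprintf("manifest '%s' line %d: unknown parameter set '%s'",
                   manifest, i + 1L, set_name))
    ann <- if (has_ann)
      case_annotation(c(df$calc_x[i], df$calc_y[i], df$calc_z[i]),
                      if (all(c("shift_x", "shift_y", "shift_z") %in% names(df)))
                        c(df$shift_x[i], df$shift_y[i], df$shift_z[i])
                      else c(0, 0, 0),
                      case_id = df$case[i])
    else NULL
    id <- sprintf("%s:%s", df$case[i], set_name)
    if (id %in% done_ids) next
    jobs[[length(jobs) + 1L]] <- job_message(
      id = id, ref = resolve(df$ref[i]), flt = resolve(df$flt[i]), ann = ann,
      params = sets[[set_name]],
      meta = list(case = df$case[i], set = set_name, seed = job_seed(seed, i)))
  }
  fallbacks <- if (length(sets) > 1L) sets[-1L] else list()
  completed <- if (length(jobs) > 0L) {
    q <- job_queue()
    enqueue(q, jobs)
    if (is.null(executor)) executor <- make_executor(compute_stre = compute_stre)
    run_queue(q, executor, n_workers = n_workers, max_retries = max_retries,
              fallback_sets = unname(fallbacks))
  } else list()
  rows <- lapply(completed, function(j) {
    m <- if (is.null(j$result)) list() else j$result
    g <- function(k) if (is.null(m[[k]])) NA else m[[k]]
    data.frame(id = j$id, case = if (!is.null(j$meta$case)) j$meta$case else "",
               set = if (!is.null(j$meta$set)) j$meta$set else "",
               attempt = j$attempt, status = j$status,
               tre_mm = as.numeric(g("tre_mm")),
               ssim_before = as.numeric(g("ssim_before")),
               ssim = as.numeric(g("ssim")),
               mean_stre = as.numeric(g("mean_stre")),
               qa_pass = as.logical(g("qa_pass")),
               jacobian_min = as.numeric(g("jacobian_min")),
               seconds = as.numeric(g("seconds")),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L)
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(id = character(0), case = character(0),
               set = character(0), attempt = integer(0),
               status = character(0), tre_mm = numeric(0),
               ssim_before = numeric(0), ssim = numeric(0),
               mean_stre = numeric(0), qa_pass = logical(0),
               jacobian_min = numeric(0), seconds = numeric(0))
  if (!is.null(ledger)) {
    all_rows <- if (!is.null(prior)) rbind(prior, out) else out
    utils::write.table(all_rows, ledger, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  if (!is.null(prior)) out <- rbind(prior, out)
  rownames(out) <- NULL
  out
}
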