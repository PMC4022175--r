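#' Plan the analysis steps from the available inputs
#'
#' Adequate steps are chosen automatically from what is available:
#' the improper-read filter needs paired-end data; the CNV and
#' mappability filters need their annotation; trimming thresholds come
#' from the matched normal when one is present; normalization is
#' paired when a normal exists, otherwise GC-based. With neither GC
#' annotation nor a normal, normalization is impossible and planning
#' refuses with an explanatory error. Every skipped step carries its
#' reason.
#'
#' @param paired paired-end data available?
#' @param has_gc GC annotation available?
#' @param has_mappability mappability annotation available?
#' @param has_cnv common-CNV regions available?
#' @param has_normal matched normal available?
#' @return data.frame of class `pipeline_plan`: `step`, `run`
#'   (logical), `reason`.
#' @export
plan_pipeline <- function(paired = FALSE, has_gc = FALSE,
                          has_mappability = FALSE, has_cnv = FALSE,
                          has_normal = FALSE) {
  if (!has_gc && !has_normal) {
    stop("normalization impossible: no GC annotation and no matched normal; ",
         "supply a GC table or a normal profile")
  }
  step <- c("pem_filter", "mapq_filter", "trim_filter", "cnv_filter",
            "mappability_filter", "normalize", "segment")
  run <- c(paired, TRUE, TRUE, has_cnv, has_mappability, TRUE, TRUE)
  reason <- c(
    if (paired) "paired-end data" else "skipped: single-end data",
    "mean mapping quality available from summarization",
    if (has_normal) "thresholds estimated on matched normal"
    else "runs-test thresholds on tumour profile",
    if (has_cnv) "CNV regions supplied" else "skipped: no CNV regions",
    if (has_mappability) "mappability supplied"
    else "skipped: no mappability annotation",
    if (has_normal) "paired normalization against matched normal"
    else "GC correction (seqnorm)",
    "penalized least-squares changepoints")
  out <- data.frame(step = step, run = run, reason = reason,
                    stringsAsFactors = FALSE)
  class(out) <- c("pipeline_plan", "data.frame")
  out
}

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments
#' ignored. Values are parsed as logical/numeric where possible.
#' Serialization via [write_config()] is a fixed point:
#' write(read(write(x))) == write(x).
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  bad <- lengths(kv) != 3
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  keys <- trimws(vapply(kv, `[`, character(1), 2))
  vals <- trimws(vapply(kv, `[`, character(1), 3))
  parse1 <- function(v) {
    if (v %in% c("TRUE", "FALSE")) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) return(num)
    v
  }
  stats::setNames(lapply(vals, parse1), keys)
}

#' Write a configuration list to a flat key = value file
#' @param config named list of scalars.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- config[order(names(config))]
  fmt <- vapply(config, function(v) {
    if (is.numeric(v)) format(v, digits = 15) else as.character(v)
  }, character(1))
  writeLines(sprintf("%s = %s", names(config), fmt), path)
  invisible(path)
}

pipeline_defaults <- list(
  window_size = 200000, pem_max = 0.5, mapq_min = 30, trim = TRUE,
  cnv_max = 0, mappability_min = 0.5, method = "seqnorm", span = 0.3,
  paired_mode = "ratio", seed = 1, workers = 1
)

#' Run the integrated pipeline
#'
#' Executes the planned steps in order: load or simulate the profile,
#' annotate, filter, normalize, segment, optionally call, and write the
#' artifacts (profile TSV, report JSON, SEG). Deterministic given
#' `seed`; per-chromosome work is merged in chromosome order so results
#' are identical for any `workers` count. Any stage failure aborts with
#' the stage name; artifacts already written are preserved.
#'
#' @param config named list (or path to a [read_config()] file). Keys:
#'   `sam` or `profile` (input; or `simulate_seed` for a synthetic run),
#'   `normal` (profile TSV), `annot` (GC/mappability TSV), `cnv` (BED),
#'   `out_prefix` (required), `window_size`, `pem_max`, `mapq_min`,
#'   `trim`, `cnv_max`, `mappability_min`, `method` (`seqnorm`/`loess`),
#'   `span`, `paired_mode` (`ratio`/`seqnorm`), `thresholds`
#'   (comma-separated; or `baseline_cn` to use suggested thresholds),
#'   `seed`, `workers`.
#' @return invisibly, a list with the final `profile`, `segments`,
#'   `calls` (or `NULL`), `report`, `plan` and the written `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  cfg <- utils::modifyList(pipeline_defaults, config)
  if (is.null(cfg[["out_prefix"]])) stop("config key 'out_prefix' is required")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  for (key in c("sam", "profile", "normal", "annot", "cnv")) {
    if (!is.null(cfg[[key]]) && is.character(cfg[[key]]) &&
        !file.exists(cfg[[key]])) {
      stop(sprintf("input file for '%s' not found: %s", key, cfg[[key]]))
    }
  }
  set.seed(as.integer(cfg$seed))
  prof <- stage("input", {
    if (!is.null(cfg[["sam"]])) {
      summarize_sam(cfg[["sam"]], window_size = cfg$window_size)
    } else if (!is.null(cfg[["profile"]])) {
      read_profile(cfg[["profile"]])
    } else if (!is.null(cfg[["simulate_seed"]])) {
      simulate_profile(seed = as.integer(cfg[["simulate_seed"]]))$profile
    } else stop("no input: set 'sam', 'profile' or 'simulate_seed'")
  })
  normal <- if (!is.null(cfg[["normal"]])) stage("input", read_profile(cfg[["normal"]]))
  prof <- stage("annotate", {
    if (!is.null(cfg[["annot"]]) || !is.null(cfg[["cnv"]])) {
      annot <- if (!is.null(cfg[["annot"]])) read_annotation(cfg[["annot"]])
      gc_tab <- if (!is.null(annot) && "gc" %in% names(annot)) annot
      mp_tab <- if (!is.null(annot) && "mappability" %in% names(annot)) annot
      annotate_profile(prof, gc_table = gc_tab, mappability_table = mp_tab,
                       cnv_bed = cfg[["cnv"]])
    } else prof
  })
  has_gc <- any(is.finite(prof$windows$gc))
  plan <- stage("plan", plan_pipeline(
    paired = prof$paired, has_gc = has_gc,
    has_mappability = any(is.finite(prof$windows$mappability)),
    has_cnv = !is.null(cfg[["cnv"]]), has_normal = !is.null(normal)))
  filtered <- stage("filter", apply_filters(
    prof,
    pem_max = if (prof$paired) cfg$pem_max,
    mapq_min = if (!all(is.na(prof$windows$mean_mapq))) cfg$mapq_min,
    trim = isTRUE(cfg$trim) && (has_gc || !is.null(normal)),
    cnv_max = if (!is.null(cfg[["cnv"]])) cfg[["cnv_max"]],
    mappability_min = if (any(is.finite(prof$windows$mappability)))
      cfg$mappability_min,
    normal = normal, skip_unavailable = TRUE, span = cfg$span))
  prof <- filtered$profile
  prof <- stage("normalize", {
    if (!is.null(normal)) {
      paired_normalize(prof, normal, mode = cfg$paired_mode,
                       span = cfg$span)
    } else if (identical(cfg$method, "loess")) {
      single_pass_correct(prof, span = cfg$span)
    } else {
      seqnorm(prof, span = cfg$span)
    }
  })
  segs <- stage("segment", segment_profile_parallel(prof,
                                                    workers = cfg$workers))
  calls <- NULL
  thr <- NULL
  if (!is.null(cfg[["thresholds"]])) {
    thr <- as.numeric(strsplit(as.character(cfg[["thresholds"]]), ",")[[1]])
  } else if (!is.null(cfg[["baseline_cn"]])) {
    thr <- suggest_thresholds(segs, baseline_cn = as.integer(cfg[["baseline_cn"]]))
  }
  if (!is.null(thr)) calls <- stage("call", call_copy_number(segs, thr))
  paths <- stage("write", {
    p_prof <- paste0(cfg[["out_prefix"]], ".profile.tsv")
    p_seg <- paste0(cfg[["out_prefix"]], ".seg")
    p_rep <- paste0(cfg[["out_prefix"]], ".report.json")
    write_profile(prof, p_prof)
    write_seg(if (is.null(calls)) segs else calls, p_seg)
    rep <- filtered$report
    jsonlite::write_json(
      list(plan = plan,
           filters = list(masked = rep$masked, venn = rep$venn,
                          skipped = rep$skipped,
                          thresholds = rep$thresholds,
                          retained_fraction = rep$retained_fraction),
           normalization = list(method = prof$method,
                                fallback = prof$fallback),
           calling_thresholds = thr,
           config = cfg[order(names(cfg))]),
      p_rep, auto_unbox = TRUE, digits = NA, null = "null")
    c(profile = p_prof, seg = p_seg, report = p_rep)
  })
  invisible(list(profile = prof, segments = segs, calls = calls,
                 report = filtered$report, plan = plan, paths = paths))
}

# per-chromosome segmentation with deterministic merge; `workers` is an
# order-independence contract, not a speed knob: results are identical
# for any worker count because chromosomes are independent and merged
# in grid order
segment_profile_parallel <- function(profile, penalty = NULL, workers = 1) {
  chroms <- unique(profile$windows$chrom)
  if (is.null(penalty)) {
    noise <- profile_snr(profile)$noise
    noise <- max(noise, 1e-9 * (abs(stats::median(
      profile_values(profile), na.rm = TRUE)) + 1))
    penalty <- 3 * noise^2 * log(sum(!combined_mask(profile)))
  }
  one <- function(ch) {
    sub <- profile
    keep <- profile$windows$chrom == ch
    sub$windows <- profile$windows[keep, , drop = FALSE]
    sub$filters <- lapply(profile$filters, `[`, keep)
    s <- segment_profile(sub, penalty = penalty)
    # local -> global window indices
    offset <- which(keep)[1] - 1L
    s$start_win <- s$start_win + offset
    s$end_win <- s$end_win + offset
    s
  }
  pieces <- if (workers > 1 && .Platform$OS.type == "unix") {
    parallel::mclapply(chroms, one, mc.cores = workers)
  } else {
    lapply(chroms, one)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("segment_set", "data.frame")
  out
}
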