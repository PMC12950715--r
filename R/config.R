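#' Round a channel width to a hardware-friendly multiple
#'
#' Snaps `value` to the nearest multiple of `divisor` without shrinking it by
#' more than 10% (the MobileNet-family convention): the result is always a
#' multiple of `divisor`, at least `min_value`, and at least `0.9 * value`.
#'
#' @param value Positive number to round.
#' @param divisor Positive integer the result must divide by.
#' @param min_value Lower bound for the result; defaults to `divisor`.
#' @return A positive integer multiple of `divisor`.
#' @examples
#' make_divisible(36, 4)  # 36
#' make_divisible(9, 1)   # 9
#' make_divisible(18, 8)  # 24 (16 would undercut the 0.9 floor)
#' @export
make_divisible <- function(value, divisor, min_value = divisor) {
  if (!is.numeric(value) || length(value) != 1L || value <= 0)
    stop("`value` must be a single positive number", call. = FALSE)
  if (!is.numeric(divisor) || length(divisor) != 1L || divisor < 1)
    stop("`divisor` must be a positive integer", call. = FALSE)
  divisor <- as.integer(divisor)
  new_v <- max(min_value, (value + divisor / 2) %/% divisor * divisor)
  if (new_v < 0.9 * value) new_v <- new_v + divisor
  as.integer(new_v)
}

#' Derive the channel schedule for a given stem width
#'
#' The reference schedule (stem 24, multi-scale block 36, inverted-residual
#' outputs 48/72/96/120/120, head 240) is an exact multiple ladder of the stem
#' width S: msc = 1.5 S, IR outputs = (2, 3, 4, 5, 5) S, head = 10 S. Smaller
#' stems scale proportionally. The four multi-scale branch widths are equal
#' integer quarters of the block output, with any remainder assigned to the
#' pooling branch (deterministic tie-break).
#'
#' @param stem_channels Stem width S (positive integer, at least 4).
#' @return A `channel_schedule` list with fields `stem_out`, `msc_out`,
#'   `msc_branch_widths` (length 4), `ir_out` (length 5), `ir_strides`
#'   (always `c(2, 2, 2, 2, 1)`) and `head_out`.
#' @examples
#' derive_channel_schedule(24)
#' @export
derive_channel_schedule <- function(stem_channels) {
  if (!is.numeric(stem_channels) || length(stem_channels) != 1L ||
      stem_channels < 4 || stem_channels != round(stem_channels))
    stop("`stem_channels` must be a single integer >= 4", call. = FALSE)
  s <- as.integer(stem_channels)
  msc <- as.integer(round(1.5 * s))
  base <- msc %/% 4L
  rem <- msc %% 4L
  branches <- c(base, base, base, base + rem)  # remainder to the pooling branch
  sched <- list(
    stem_out = s,
    msc_out = msc,
    msc_branch_widths = as.integer(branches),
    ir_out = as.integer(c(2L, 3L, 4L, 5L, 5L) * s),
    ir_strides = c(2L, 2L, 2L, 2L, 1L),
    head_out = 10L * s
  )
  class(sched) <- "channel_schedule"
  sched
}

ABLATION_KINDS <- c("none", "no_msc", "no_attention", "no_depthwise",
                    "no_final_projection")

#' Define an architecture configuration
#'
#' An `arch_config` is one design point of the network family: the inverted
#' residual expansion ratio E, the channel-attention reduction ratio R and the
#' stem width S, plus the derived channel schedule and task parameters.
#'
#' @param expand_ratio Expansion ratio E inside inverted residual blocks
#'   (grid values 3, 4, 6; default 4).
#' @param reduction_ratio Channel-attention bottleneck reduction R
#'   (grid values 4, 8, 16; default 8).
#' @param stem_channels Stem width S (grid values 8, 16, 24; default 24).
#' @param num_classes Number of output classes (default 9).
#' @param input_side Square input side in pixels (default 224).
#' @param dropout_p Dropout probability on the pooled feature vector
#'   (default 0.2).
#' @param ablation One of `"none"`, `"no_msc"`, `"no_attention"`,
#'   `"no_depthwise"`, `"no_final_projection"`.
#' @param schedule Optional pre-built `channel_schedule`; derived from
#'   `stem_channels` when `NULL`.
#' @return An `arch_config` object.
#' @examples
#' cfg <- arch_config()           # the default E4_R8_S24 design point
#' cfg$id
#' @export
arch_config <- function(expand_ratio = 4, reduction_ratio = 8,
                        stem_channels = 24, num_classes = 9,
                        input_side = 224, dropout_p = 0.2,
                        ablation = "none", schedule = NULL) {
  cfg <- list(
    expand_ratio = as.integer(expand_ratio),
    reduction_ratio = as.integer(reduction_ratio),
    stem_channels = as.integer(stem_channels),
    num_classes = as.integer(num_classes),
    input_side = as.integer(input_side),
    dropout_p = as.numeric(dropout_p),
    ablation = match.arg(ablation, ABLATION_KINDS),
    schedule = if (is.null(schedule)) derive_channel_schedule(stem_channels) else schedule
  )
  cfg$head_channels <- cfg$schedule$head_out
  cfg$id <- sprintf("E%d_R%d_S%d", cfg$expand_ratio, cfg$reduction_ratio,
                    cfg$stem_channels)
  if (cfg$ablation != "none") cfg$id <- paste0(cfg$id, "__", cfg$ablation)
  class(cfg) <- "arch_config"
  validate_arch_config(cfg)
  cfg
}

validate_arch_config <- function(cfg) {
  stopifnot(inherits(cfg, "arch_config"))
  with(cfg, {
    if (expand_ratio < 1 || reduction_ratio < 1 || stem_channels < 4)
      stop("E, R must be positive and S >= 4", call. = FALSE)
    if (num_classes < 2) stop("`num_classes` must be >= 2", call. = FALSE)
    if (dropout_p < 0 || dropout_p > 1)
      stop("`dropout_p` must lie in [0, 1]", call. = FALSE)
    if (input_side < 32) stop("`input_side` must be >= 32", call. = FALSE)
  })
  sch <- cfg$schedule
  if (sum(sch$msc_branch_widths) != sch$msc_out)
    stop("branch widths must sum to the multi-scale output width", call. = FALSE)
  if (!identical(as.integer(sch$ir_strides), c(2L, 2L, 2L, 2L, 1L)))
    stop("inverted residual strides must be 2,2,2,2,1", call. = FALSE)
  invisible(cfg)
}

#' @export
print.arch_config <- function(x, ...) {
  cat(sprintf("<arch_config %s>  E=%d R=%d S=%d classes=%d input=%dpx ablation=%s\n",
              x$id, x$expand_ratio, x$reduction_ratio, x$stem_channels,
              x$num_classes, x$input_side, x$ablation))
  sch <- x$schedule
  cat(sprintf("  schedule: stem %d | msc %d [%s] | ir %s | head %d\n",
              sch$stem_out, sch$msc_out,
              paste(sch$msc_branch_widths, collapse = ","),
              paste(sch$ir_out, collapse = ","), sch$head_out))
  invisible(x)
}

#' Enumerate the full hyperparameter grid
#'
#' Returns the 27 design points of the full factorial over E in {3, 4, 6},
#' R in {4, 8, 16} and S in {8, 16, 24}, each with a stable `E{E}_R{R}_S{S}`
#' identifier.
#'
#' @param input_side Input side used for every config (default 224).
#' @param num_classes Number of classes (default 9).
#' @return A named list of 27 `arch_config` objects.
#' @export
enumerate_grid <- function(input_side = 224, num_classes = 9) {
  grid <- expand.grid(S = c(8L, 16L, 24L), R = c(4L, 8L, 16L),
                      E = c(3L, 4L, 6L))
  cfgs <- lapply(seq_len(nrow(grid)), function(i) {
    arch_config(expand_ratio = grid$E[i], reduction_ratio = grid$R[i],
                stem_channels = grid$S[i], input_side = input_side,
                num_classes = num_classes)
  })
  names(cfgs) <- vapply(cfgs, `[[`, "", "id")
  cfgs
}

#' Build one of the four ablation variants of the default configuration
#'
#' Each ablation removes or replaces one structural component of the default
#' (E=4, R=8, S=24) network: `no_msc` replaces the multi-scale block with a
#' single 3x3 branch of equal output width, `no_attention` drops every
#' channel-attention gate, `no_depthwise` swaps depthwise convolutions for
#' standard 3x3 convolutions of identical widths, and `no_final_projection`
#' omits the head 1x1 projection so the last feature maps feed the pooling
#' and classifier directly.
#'
#' @param kind One of `"no_msc"`, `"no_attention"`, `"no_depthwise"`,
#'   `"no_final_projection"`.
#' @param ... Passed to [arch_config()] (e.g. `input_side`).
#' @return An `arch_config` with the ablation flag set.
#' @export
make_ablation_config <- function(kind, ...) {
  kind <- match.arg(kind, ABLATION_KINDS[-1])
  arch_config(ablation = kind, ...)
}

#' Serialize a configuration to a flat YAML file
#' @param config An `arch_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_arch_config(config)
  flat <- config[c("expand_ratio", "reduction_ratio", "stem_channels",
                   "num_classes", "input_side", "dropout_p", "ablation", "id")]
  yaml::write_yaml(flat, path)
  invisible(path)
}

#' Read a configuration written by [write_config()]
#' @param path YAML file path.
#' @return An `arch_config`.
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  arch_config(expand_ratio = flat$expand_ratio,
              reduction_ratio = flat$reduction_ratio,
              stem_channels = flat$stem_channels,
              num_classes = flat$num_classes,
              input_side = flat$input_side,
              dropout_p = flat$dropout_p,
              ablation = flat$ablation)
}

#' Write the 27 grid configurations (plus ablations) to a directory
#' @param dir Output directory (created if missing).
#' @param ablations Also write the four ablation variants (default TRUE).
#' @return Character vector of files written, invisibly.
#' @export
write_grid_configs <- function(dir, ablations = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfgs <- enumerate_grid()
  if (ablations)
    cfgs <- c(cfgs, lapply(ABLATION_KINDS[-1], make_ablation_config))
  paths <- vapply(cfgs, function(cfg) {
    p <- file.path(dir, paste0(cfg$id, ".yaml"))
    write_config(cfg, p)
    p
  }, "")
  invisible(paths)
}
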