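#' Designated action channels
#'
#' Two fixed neighbouring channels per hemisphere encode the basic actions.
#' The encoding is contralateral: the 'turn left' channel of the *right*
#' hemisphere drives the left action command, the 'turn right' channel of
#' the *left* hemisphere drives the right action command. Both hemispheres
#' use the same grid coordinates.
#'
#' @param grid A [channel_grid()].
#' @param turn_left,turn_right `(row, col)` coordinates of the two channels;
#'   defaults are the horizontally adjacent pair (3,3) and (3,4).
#' @return Named integer vector `c(turn_left = ..., turn_right = ...)`.
#' @export
action_channels <- function(grid = channel_grid(),
                            turn_left = c(3, 3), turn_right = c(3, 4)) {
  ch <- c(turn_left = channel_index(turn_left[1], turn_left[2], grid),
          turn_right = channel_index(turn_right[1], turn_right[2], grid))
  if (ch[1] == ch[2]) stop("action channels must differ")
  ch
}

new_protocol <- function(name, duration_ms, blocks, modifiers = list()) {
  structure(list(name = name, duration_ms = duration_ms,
                 blocks = blocks, modifiers = modifiers),
            class = "stimulus_protocol")
}

empty_blocks <- function() {
  data.frame(hemisphere = character(), type = character(),
             channels = character(), kind = character(),
             amplitude_pA = numeric(), rate_hz = numeric(),
             weight_nS = numeric(), t_start_ms = numeric(),
             t_stop_ms = numeric(), stringsAsFactors = FALSE)
}

block_row <- function(hemisphere, type, channels, kind,
                      amplitude_pA = NA_real_, rate_hz = NA_real_,
                      weight_nS = NA_real_, t_start_ms, t_stop_ms) {
  stopifnot(t_start_ms < t_stop_ms)
  data.frame(hemisphere = hemisphere, type = type,
             channels = as.character(channels), kind = kind,
             amplitude_pA = as.numeric(amplitude_pA),
             rate_hz = as.numeric(rate_hz),
             weight_nS = as.numeric(weight_nS),
             t_start_ms = as.numeric(t_start_ms),
             t_stop_ms = as.numeric(t_stop_ms), stringsAsFactors = FALSE)
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("<stimulus_protocol> %s: %d block(s), %g ms\n",
              x$name, if (is.null(x$blocks)) 0L else nrow(x$blocks),
              x$duration_ms))
  invisible(x)
}

#' Catalog of the global (whole-hemisphere) stimulation paradigms
#'
#' Current amplitudes in pA applied to the D1/D2 populations of the left
#' (L) and right (R) hemisphere during the stimulation window; `NA` means
#' no current.
#'
#' @return data.frame with one row per paradigm.
#' @export
global_paradigm_catalog <- function() {
  data.frame(
    paradigm = c("no_stim", "bilateral_D1", "bilateral_D2",
                 "unilateral_D1D2_inh", "unilateral_D1_inh",
                 "unilateral_D2_inh", "unilateral_D1_exc",
                 "unilateral_D2_exc"),
    L_D1 = c(NA, 115, NA, -175, -175, NA, 125, NA),
    L_D2 = c(NA, NA, 160, -100, NA, -100, NA, 110),
    R_D1 = c(NA, 115, NA, NA, NA, NA, NA, NA),
    R_D2 = c(NA, NA, 160, NA, NA, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Catalog of the channel-targeted (Poisson input) paradigms
#'
#' Rates in spikes/s of the excitatory Poisson trains delivered to the
#' designated action channels. The sequence paradigms stimulate the left
#' hemisphere's 'turn right' channel for 5 s, then (after a 1 s pause) the
#' right hemisphere's 'turn left' channel for 5 s. 'Competing actions'
#' stimulates both action channels of both hemispheres simultaneously for
#' 16 s.
#'
#' @return data.frame with one row per paradigm.
#' @export
sequence_paradigm_catalog <- function() {
  data.frame(
    paradigm = c("sequences_D1", "sequences_D2", "sequences_D1D2",
                 "competing_actions"),
    rate_D1 = c(300, NA, 300, 250),
    rate_D2 = c(NA, 120, 150, 200),
    phase_s = c(5, 5, 5, 16),
    stringsAsFactors = FALSE
  )
}

#' Global stimulation paradigms
#'
#' Builds the whole-hemisphere DC-current paradigms: the stated current to
#' the stated populations of all 36 channels, on `[5 s, 15 s]` of a 20 s
#' run. `no_stim` has an empty block list (background only).
#'
#' @param name One of the paradigms in [global_paradigm_catalog()].
#' @param duration_ms Run duration (default 20000).
#' @param stim_window_ms Stimulation window (default `c(5000, 15000)`).
#' @return A `stimulus_protocol`.
#' @export
make_global_paradigm <- function(name, duration_ms = 20000,
                                 stim_window_ms = c(5000, 15000)) {
  cat_ <- global_paradigm_catalog()
  if (!name %in% cat_$paradigm)
    stop("unknown paradigm '", name, "'; valid names: ",
         paste(cat_$paradigm, collapse = ", "))
  row <- cat_[cat_$paradigm == name, ]
  blocks <- empty_blocks()
  for (col in c("L_D1", "L_D2", "R_D1", "R_D2")) {
    amp <- row[[col]]
    if (!is.na(amp)) {
      hemi <- substr(col, 1, 1)
      type <- substr(col, 3, 4)
      blocks <- rbind(blocks,
                      block_row(hemi, type, "all", "dc", amplitude_pA = amp,
                                t_start_ms = stim_window_ms[1],
                                t_stop_ms = stim_window_ms[2]))
    }
  }
  new_protocol(name, duration_ms, blocks)
}

#' Channel-targeted sequence and competition paradigms
#'
#' Cortical-like input is modelled as excitatory Poisson spike trains to the
#' designated action channels (synaptic weight `stim_weight_nS`, reusing the
#' background weight by default). Sequences: first the left hemisphere's
#' 'turn right' channel on `[5 s, 10 s]`, then the right hemisphere's 'turn
#' left' channel on `[11 s, 16 s]`. Competing actions: both action channels
#' of both hemispheres on `[2 s, 18 s]`.
#'
#' @param name One of the paradigms in [sequence_paradigm_catalog()].
#' @param grid A [channel_grid()] (to locate the action channels).
#' @param channels Action channels as returned by [action_channels()].
#' @param duration_ms Run duration (default 20000).
#' @param stim_weight_nS Synaptic weight of the stimulus trains (2.5 nS).
#' @return A `stimulus_protocol`.
#' @export
make_sequence_paradigm <- function(name, grid = channel_grid(),
                                   channels = action_channels(grid),
                                   duration_ms = 20000,
                                   stim_weight_nS = 2.5) {
  cat_ <- sequence_paradigm_catalog()
  if (!name %in% cat_$paradigm)
    stop("unknown paradigm '", name, "'; valid names: ",
         paste(cat_$paradigm, collapse = ", "))
  row <- cat_[cat_$paradigm == name, ]
  blocks <- empty_blocks()
  add <- function(b, hemi, type, ch, rate, t0, t1)
    rbind(b, block_row(hemi, type, ch, "poisson", rate_hz = rate,
                       weight_nS = stim_weight_nS,
                       t_start_ms = t0, t_stop_ms = t1))
  if (name == "competing_actions") {
    both <- paste(channels[["turn_left"]], channels[["turn_right"]], sep = ",")
    for (hemi in c("L", "R")) {
      blocks <- add(blocks, hemi, "D1", both, row$rate_D1, 2000, 18000)
      blocks <- add(blocks, hemi, "D2", both, row$rate_D2, 2000, 18000)
    }
  } else {
    ph1 <- c(5000, 10000); ph2 <- c(11000, 16000)
    for (ty in c("D1", "D2")) {
      rate <- row[[paste0("rate_", ty)]]
      if (is.na(rate)) next
      blocks <- add(blocks, "L", ty, channels[["turn_right"]], rate,
                    ph1[1], ph1[2])
      blocks <- add(blocks, "R", ty, channels[["turn_left"]], rate,
                    ph2[1], ph2[2])
    }
  }
  new_protocol(name, duration_ms, blocks)
}

#' Simulated GABA-antagonist (disinhibition) experiment
#'
#' All neurons receive a 140 pA current injection for 200 ms at 5 s
#' (control) and again at 15 s (antagonist). From 10 s onward all
#' inhibitory weights are scaled to 20% of their value (the antagonist);
#' the background input is scaled to 25% for the whole run to mimic the
#' low spontaneous activity of a slice preparation.
#'
#' @param duration_ms Run duration (default 20000).
#' @param amp_pA Stimulus amplitude (140).
#' @param bout_ms Stimulus duration (200).
#' @param inh_scale Antagonist inhibition factor (0.2).
#' @param inh_scale_from_ms Time from which the antagonist acts (10000,
#'   the midpoint between the two stimuli).
#' @param background_scale Background scaling (0.25).
#' @return A `stimulus_protocol` with modifiers.
#' @export
make_gaba_experiment <- function(duration_ms = 20000, amp_pA = 140,
                                 bout_ms = 200, inh_scale = 0.2,
                                 inh_scale_from_ms = 10000,
                                 background_scale = 0.25) {
  blocks <- rbind(
    block_row("all", "all", "all", "dc", amplitude_pA = amp_pA,
              t_start_ms = 5000, t_stop_ms = 5000 + bout_ms),
    block_row("all", "all", "all", "dc", amplitude_pA = amp_pA,
              t_start_ms = 15000, t_stop_ms = 15000 + bout_ms)
  )
  new_protocol("gaba_antagonist", duration_ms, blocks,
               modifiers = list(inh_scale = inh_scale,
                                inh_scale_from_ms = inh_scale_from_ms,
                                background_scale = background_scale))
}

#' List all stimulation paradigms
#' @return Character vector of paradigm names.
#' @export
list_paradigms <- function() {
  c(global_paradigm_catalog()$paradigm, sequence_paradigm_catalog()$paradigm,
    "gaba_antagonist")
}

#' Build a protocol by name
#' @param name Any name from [list_paradigms()].
#' @param ... Passed to the specific constructor.
#' @return A `stimulus_protocol`.
#' @export
make_paradigm <- function(name, ...) {
  if (name %in% global_paradigm_catalog()$paradigm)
    make_global_paradigm(name, ...)
  else if (name %in% sequence_paradigm_catalog()$paradigm)
    make_sequence_paradigm(name, ...)
  else if (name == "gaba_antagonist")
    make_gaba_experiment(...)
  else
    stop("unknown paradigm '", name, "'; valid names: ",
         paste(list_paradigms(), collapse = ", "))
}

#' Serialize / parse a protocol as JSON text
#'
#' Round-trip safe: `read_protocol(write_protocol(p, f))` reproduces `p`.
#'
#' @param protocol A `stimulus_protocol`.
#' @param path File path.
#' @return `write_protocol` the path invisibly; `read_protocol` the protocol.
#' @export
write_protocol <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  blocks <- if (is.null(x$blocks) || length(x$blocks) == 0) empty_blocks()
            else as.data.frame(x$blocks, stringsAsFactors = FALSE)
  if (nrow(blocks)) {
    tmpl <- empty_blocks()
    for (cn in names(tmpl)) {
      if (is.null(blocks[[cn]])) blocks[[cn]] <- NA
      mode_target <- class(tmpl[[cn]])
      blocks[[cn]] <- if (mode_target == "numeric") as.numeric(blocks[[cn]])
                      else as.character(blocks[[cn]])
    }
    blocks <- blocks[, names(tmpl)]
  }
  mods <- if (is.null(x$modifiers) || length(x$modifiers) == 0) list()
          else x$modifiers
  new_protocol(x$name, x$duration_ms, blocks, mods)
}
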