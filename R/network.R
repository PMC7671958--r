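#' Build a network configuration
#'
#' Assembles the compartment table, chemical synapses, electrical couplings
#' and external-drive attachments for one of the studied network reductions:
#'
#' * `"full4"` — all four cells (RS, FS, SI and the four-compartment IB);
#'   one drive slot `input1` projecting to RS. Leave the drive empty for the
#'   autonomous beta1 network.
#' * `"fs_si_ib"` — RS removed; `input1` projects directly to FS and SI with
#'   the RS-output synapse kinetics.
#' * `"fs_si_2inputs"` — IB also removed; a second drive `input2` projects
#'   to FS and SI with the IB-output synapse kinetics.
#' * `"si_only"` — a single SI cell; `input1` excitatory, `input2`
#'   inhibitory with the FS-output synapse kinetics.
#' * `"multiplex3"` — three copies of the `si_only` circuit plus one output
#'   RS cell receiving excitatory synapses from all three SI cells; drives
#'   `input1a/b/c` (independent fast streams) and `input2a/b/c`
#'   (phase-shifted copies of the slow stream).
#'
#' @param config_id One of `"full4"`, `"fs_si_ib"`, `"fs_si_2inputs"`,
#'   `"si_only"`, `"multiplex3"`.
#' @param params Parameter set from [pgParams()] (possibly modified).
#' @param variant Optional named variant: `"weak_fs_si"` halves the FS-to-SI
#'   (and inhibitory input-2) conductance; `"fast_ar"` speeds up the IB
#'   dendritic h-current kinetics by a third; `"strong_input"` scales the
#'   input-1 drive strength by 1.3 (the regime where the slow cell can fire on
#'   every fast cycle).
#' @return An object of class `network_spec`: list with `config`, `comp`
#'   (matrix, one row per compartment), `syn` (data frame), `gap` (data
#'   frame), `drives` (drive slot names) and `params_version`.
#' @export
buildNetwork <- function(config_id, params = pgParams(), variant = NULL) {
  if (!is.null(variant)) {
    variant <- match.arg(variant, c("weak_fs_si", "fast_ar", "strong_input"))
    if (variant == "weak_fs_si") {
      params$syn$FS_SI$g <- params$syn$FS_SI$g / 2
      params$syn$IN2i_SI$g <- params$syn$IN2i_SI$g / 2
    } else if (variant == "fast_ar") {
      params$cells$IBda["ar_tsc"] <- params$cells$IBda["ar_tsc"] * 2 / 3
      params$cells$IBdb["ar_tsc"] <- params$cells$IBdb["ar_tsc"] * 2 / 3
    } else if (variant == "strong_input") {
      params$syn$IN1_SI$g <- params$syn$IN1_SI$g * 1.3
      params$syn$IN1_FS$g <- params$syn$IN1_FS$g * 1.3
    }
  }
  cl <- params$cells
  ib_comps <- c("IBs", "IBa", "IBda", "IBdb")
  ib_syn <- list(c("SI", "IBa", "SI_IB"), c("IBa", "FS", "IB_FS"),
                 c("IBa", "SI", "IB_SI"), c("IBa", "IBdb", "IB_a_db"))
  cfg <- switch(config_id,
    full4 = list(
      comps = c("RS", "FS", "SI", ib_comps),
      syn = c(list(c("RS", "FS", "RS_FS"), c("RS", "SI", "RS_SI"),
                   c("FS", "RS", "FS_RS"), c("FS", "SI", "FS_SI"),
                   c("FS", "FS", "FS_FS")),
              ib_syn,
              list(c("input1", "RS", "IN_RS"))),
      drives = "input1"
    ),
    fs_si_ib = list(
      comps = c("FS", "SI", ib_comps),
      syn = c(list(c("FS", "SI", "FS_SI"), c("FS", "FS", "FS_FS")),
              ib_syn,
              list(c("input1", "FS", "IN1_FS"), c("input1", "SI", "IN1_SI"))),
      drives = "input1"
    ),
    fs_si_2inputs = list(
      comps = c("FS", "SI"),
      syn = list(c("FS", "SI", "FS_SI"), c("FS", "FS", "FS_FS"),
                 c("input1", "FS", "IN1_FS"), c("input1", "SI", "IN1_SI"),
                 c("input2", "FS", "IN2_FS"), c("input2", "SI", "IN2_SI")),
      drives = c("input1", "input2")
    ),
    si_only = list(
      comps = "SI",
      syn = list(c("input1", "SI", "IN1_SI"), c("input2", "SI", "IN2i_SI")),
      drives = c("input1", "input2")
    ),
    multiplex3 = list(
      comps = c("SI1", "SI2", "SI3", "RS"),
      syn = c(
        lapply(1:3, function(k) c(paste0("input1", letters[k]),
                                  paste0("SI", k), "IN1_SI")),
        lapply(1:3, function(k) c(paste0("input2", letters[k]),
                                  paste0("SI", k), "IN2i_SI")),
        lapply(1:3, function(k) c(paste0("SI", k), "RS", "SI_RS"))
      ),
      drives = c(paste0("input1", letters[1:3]), paste0("input2", letters[1:3]))
    ),
    stop("unknown config_id: ", config_id)
  )

  # compartment table: multiplex SI copies reuse the SI parameters and the
  # multiplex output cell uses the dedicated relay entry
  row_of <- function(nm) {
    base <- if (grepl("^SI[0-9]$", nm)) "SI"
            else if (nm == "RS" && config_id == "multiplex3") "RSout"
            else nm
    if (is.null(cl[[base]]))
      stop("missing parameter entry for compartment '", base, "'")
    cl[[base]]
  }
  comp <- do.call(rbind, lapply(cfg$comps, row_of))
  rownames(comp) <- cfg$comps
  colnames(comp) <- .pg_par_cols

  syn <- do.call(rbind, lapply(cfg$syn, function(sdef) {
    sp <- params$syn[[sdef[3]]]
    if (is.null(sp))
      stop("missing parameter entry for synapse '", sdef[3], "'")
    is_drive <- sdef[1] %in% cfg$drives
    if (!is_drive && !(sdef[1] %in% cfg$comps))
      stop("synapse source '", sdef[1], "' is not a compartment or drive")
    if (!(sdef[2] %in% cfg$comps))
      stop("synapse target '", sdef[2], "' is not a compartment")
    data.frame(src = sdef[1], tgt = sdef[2], is_drive = is_drive,
               g = sp$g, V0 = sp$V0, tau_d = sp$tau_d, tau_r = sp$tau_r,
               stringsAsFactors = FALSE)
  }))
  rownames(syn) <- vapply(cfg$syn, function(s) paste0(s[1], ">", s[2]),
                          character(1))

  gap <- if (all(ib_comps %in% cfg$comps)) {
    data.frame(i = c("IBs", "IBs", "IBs"), j = c("IBa", "IBda", "IBdb"),
               g = c(params$gap$IBs_IBa, params$gap$IBs_IBda,
                     params$gap$IBs_IBdb), stringsAsFactors = FALSE)
  } else {
    data.frame(i = character(0), j = character(0), g = numeric(0))
  }

  structure(list(config = config_id, comp = comp, syn = syn, gap = gap,
                 drives = cfg$drives, params_version = params$version),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("network_spec '%s' (parameter set v%s)\n", x$config,
              x$params_version))
  cat(sprintf("  %d compartments: %s\n", nrow(x$comp),
              paste(rownames(x$comp), collapse = ", ")))
  cat(sprintf("  %d chemical synapses, %d electrical couplings, drives: %s\n",
              nrow(x$syn), nrow(x$gap), paste(x$drives, collapse = ", ")))
  invisible(x)
}

#' Write a network specification as structured text
#'
#' Serializes the compartment table, synapse table and couplings as
#' tab-separated sections in a single file (a `#` section header precedes
#' each block).
#'
#' @param spec A `network_spec`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkConfig <- function(spec, path) {
  stopifnot(inherits(spec, "network_spec"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# network_spec %s v%s", spec$config,
                     spec$params_version), con)
  writeLines("# compartments", con)
  utils::write.table(data.frame(name = rownames(spec$comp), spec$comp),
                     con, sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines("# synapses", con)
  utils::write.table(spec$syn, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines("# couplings", con)
  utils::write.table(spec$gap, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
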