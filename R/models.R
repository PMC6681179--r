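#' Two-population divergence models
#'
#' A demographic model is a scenario category combined with optional
#' locus-class flags and a named vector of scaled parameters.  Categories
#' describe the timing of gene flow after the split of two populations from
#' an ancestral one:
#'
#' * `SI`  strict isolation;
#' * `IM`  isolation with continuous migration;
#' * `AM`  ancient migration: contact first, then isolation until present;
#' * `PAM` two alternating periods of contact and isolation, ending isolated;
#' * `SC`  secondary contact: isolation first, then contact until present;
#' * `PSC` two alternating periods of isolation and contact, ending in
#'   contact.
#'
#' Flags add locus-class structure or size change:
#'
#' * `ex`   exponential size change from (`nu_a1`, `nu_a2`) to (`nu1`, `nu2`)
#'   over the final `t_scg` time units;
#' * `2N`   a fraction `nr` of loci evolves with all effective sizes
#'   (including the ancestral size) multiplied by a background-selection
#'   factor `bf` in (0, 1], modelling linked selection;
#' * `2M2P` fractions `P1` and `P2` of loci receive no migration into
#'   population 1 (resp. 2), modelling genomic islands resisting gene flow.
#'
#' All parameters are scaled by a reference diploid size `Nref`: sizes `nu*`
#' are relative to `Nref`, times `t_*` are in units of `2*Nref` generations,
#' and migration rates `M12`, `M21` equal `2*Nref*m` with `m` the per
#' generation migration probability into population 1 (resp. 2).  `O` in
#' (0.5, 1] is the fraction of sites whose ancestral allele was correctly
#' inferred.
#'
#' @param category One of `"SI"`, `"IM"`, `"AM"`, `"PAM"`, `"SC"`, `"PSC"`.
#' @param params Named numeric vector of scaled parameters; see Details.
#' @param flags Character vector, subset of `c("ex", "2N", "2M2P")`.
#' @return An object of class `ps_model`.
#' @examples
#' m <- demographic_model("SC", c(nu1 = 1, nu2 = 2, M12 = 4, M21 = 1,
#'                                t_iso = 0.3, t_sc = 0.05, O = 0.97))
#' build_epochs(m)
#' @export
demographic_model <- function(category, params, flags = character()) {
  category <- match.arg(category, c("SI", "IM", "AM", "PAM", "SC", "PSC"))
  if (length(flags) > 0)
    flags <- match.arg(flags, c("ex", "2N", "2M2P"), several.ok = TRUE)
  else flags <- character()
  if (category == "SI" && "2M2P" %in% flags)
    stop("SI models have no migration; the 2M2P flag cannot apply")
  need <- model_param_names(category, flags)
  params <- unlist(params)
  missing <- setdiff(need, names(params))
  if (length(missing) > 0)
    stop("missing parameters for ", category,
         paste0(flags, collapse = ""), ": ", paste(missing, collapse = ", "))
  params <- params[need]

  sizes <- grep("^nu", need, value = TRUE)
  if (any(params[sizes] <= 0)) stop("all sizes must be > 0")
  times <- grep("^t_", need, value = TRUE)
  if (any(params[times] < 0)) stop("times must be >= 0")
  migs <- intersect(c("M12", "M21"), need)
  if (length(migs) && any(params[migs] < 0))
    stop("migration rates must be >= 0")
  if (all(c("P1", "P2") %in% need)) {
    if (any(params[c("P1", "P2")] < 0) || sum(params[c("P1", "P2")]) > 1)
      stop("P1, P2 must be >= 0 with P1 + P2 <= 1")
  }
  if ("nr" %in% need && (params["nr"] < 0 || params["nr"] > 1))
    stop("nr must be in [0, 1]")
  if ("bf" %in% need && (params["bf"] <= 0 || params["bf"] > 1))
    stop("bf must be in (0, 1]")
  if ("O" %in% need && (params["O"] <= 0.5 || params["O"] > 1))
    stop("O must be in (0.5, 1]")

  structure(list(category = category, flags = sort(flags), params = params),
            class = "ps_model")
}

#' @export
print.ps_model <- function(x, ...) {
  cat("Demographic model:", model_name(x), "\n")
  print(round(x$params, 5))
  invisible(x)
}

#' Parameter names and count for a scenario
#'
#' @param category Scenario category.
#' @param flags Flag subset.
#' @return `model_param_names()`: character vector of free parameters;
#'   `model_k()`: their number (the `k` entering the AIC).
#' @export
model_param_names <- function(category, flags = character()) {
  p <- c("nu1", "nu2")
  p <- switch(category,
    SI  = c(p, "t_iso"),
    IM  = c(p, "M12", "M21", "t_sc"),
    AM  = c(p, "M12", "M21", "t_sc", "t_iso"),
    PAM = c(p, "M12", "M21", "t_sc", "t_iso"),
    SC  = c(p, "M12", "M21", "t_iso", "t_sc"),
    PSC = c(p, "M12", "M21", "t_iso", "t_sc"))
  if ("ex" %in% flags) p <- c(p, "nu_a1", "nu_a2", "t_scg")
  if ("2N" %in% flags) p <- c(p, "nr", "bf")
  if ("2M2P" %in% flags) p <- c(p, "P1", "P2")
  c(p, "O")
}

#' @rdname model_param_names
#' @export
model_k <- function(category, flags = character())
  length(model_param_names(category, flags))

model_name <- function(model) {
  fl <- model$flags
  paste0(model$category,
         if ("2N" %in% fl) "2N" else "",
         if ("2M2P" %in% fl) "2M2P" else "",
         if ("ex" %in% fl) "ex" else "")
}

#' Parse a scenario name such as "PSC2M2Pex"
#'
#' @param name Scenario name: category followed by optional `2N` or `2M2P`
#'   and optional `ex` suffixes.
#' @return List with elements `category` and `flags`.
#' @export
parse_model_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1)
  rest <- name
  flags <- character()
  if (grepl("ex$", rest)) { flags <- c(flags, "ex"); rest <- sub("ex$", "", rest) }
  if (grepl("2M2P$", rest)) { flags <- c(flags, "2M2P"); rest <- sub("2M2P$", "", rest) }
  if (grepl("2N$", rest)) { flags <- c(flags, "2N"); rest <- sub("2N$", "", rest) }
  if (!rest %in% c("SI", "IM", "AM", "PAM", "SC", "PSC"))
    stop("unknown scenario name: ", name)
  list(category = rest, flags = sort(flags))
}

#' The 34-scenario catalogue
#'
#' All combinations of the six divergence categories with the `ex` flag and
#' one of no locus-class flag, `2N`, or `2M2P`, excluding combinations the
#' category cannot express (`SI` with `2M2P`).
#'
#' @return Data frame with columns `model`, `category`, `flags` (collapsed),
#'   and `k` (free-parameter count).
#' @export
model_catalogue <- function() {
  cats <- c("SI", "IM", "AM", "PAM", "SC", "PSC")
  rows <- list()
  for (cat in cats)
    for (ex in c(FALSE, TRUE))
      for (cls in c("", "2N", "2M2P")) {
        if (cat == "SI" && cls == "2M2P") next
        flags <- c(if (ex) "ex", if (nzchar(cls)) cls)
        if (is.null(flags)) flags <- character()
        nm <- paste0(cat, cls, if (ex) "ex" else "")
        rows[[nm]] <- data.frame(model = nm, category = cat,
                                 flags = paste(flags, collapse = "+"),
                                 k = model_k(cat, flags),
                                 stringsAsFactors = FALSE)
      }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Epoch schedule of a model
#'
#' Expands a model into the ordered list of epochs from the population split
#' to the present.  Each epoch carries a duration, start and end sizes per
#' population (equal unless the epoch is an exponential-growth epoch), and
#' the two scaled migration rates.  The `ex` flag appends a growth epoch of
#' duration `t_scg` that keeps the migration regime of the last base epoch.
#'
#' @param model A [demographic_model()].
#' @param class Locus-class modifiers, a character vector from `"base"`,
#'   `"noM12"`/`"noM21"` (the 2M2P island classes with migration into
#'   population 1 resp. 2 zeroed) and `"bf"` (the 2N linked-selection class
#'   with all sizes multiplied by `bf`).
#' @return Object of class `ps_epochs`: data frame of epochs (oldest first)
#'   with attribute `nu_anc`, the ancestral size just before the split.
#' @export
build_epochs <- function(model, class = "base") {
  stopifnot(all(class %in% c("base", "noM12", "noM21", "bf")))
  p <- as.list(model$params)
  ex <- "ex" %in% model$flags
  sz <- if (ex) c(p$nu_a1, p$nu_a2) else c(p$nu1, p$nu2)
  M12 <- if (!is.null(p$M12)) p$M12 else 0
  M21 <- if (!is.null(p$M21)) p$M21 else 0
  if ("noM12" %in% class) M12 <- 0
  if ("noM21" %in% class) M21 <- 0

  ep <- function(d, m12, m21)
    data.frame(duration = d, nu1_start = sz[1], nu1_end = sz[1],
               nu2_start = sz[2], nu2_end = sz[2], M12 = m12, M21 = m21)
  base <- switch(model$category,
    SI  = list(ep(p$t_iso, 0, 0)),
    IM  = list(ep(p$t_sc, M12, M21)),
    AM  = list(ep(p$t_sc, M12, M21), ep(p$t_iso, 0, 0)),
    PAM = list(ep(p$t_sc / 2, M12, M21), ep(p$t_iso / 2, 0, 0),
               ep(p$t_sc / 2, M12, M21), ep(p$t_iso / 2, 0, 0)),
    SC  = list(ep(p$t_iso, 0, 0), ep(p$t_sc, M12, M21)),
    PSC = list(ep(p$t_iso / 2, 0, 0), ep(p$t_sc / 2, M12, M21),
               ep(p$t_iso / 2, 0, 0), ep(p$t_sc / 2, M12, M21)))
  out <- do.call(rbind, base)
  if (ex) {
    last <- out[nrow(out), ]
    growth <- data.frame(duration = p$t_scg,
                         nu1_start = p$nu_a1, nu1_end = p$nu1,
                         nu2_start = p$nu_a2, nu2_end = p$nu2,
                         M12 = last$M12, M21 = last$M21)
    out <- rbind(out, growth)
  }
  out <- out[out$duration > 0, , drop = FALSE]
  rownames(out) <- NULL
  nu_anc <- 1
  if ("bf" %in% class) {
    bf <- p$bf
    out[, c("nu1_start", "nu1_end", "nu2_start", "nu2_end")] <-
      out[, c("nu1_start", "nu1_end", "nu2_start", "nu2_end")] * bf
    nu_anc <- bf
  }
  structure(out, nu_anc = nu_anc, class = c("ps_epochs", "data.frame"))
}

# Locus-class mixture of a model: weights and per-class epoch modifiers.
# The 2M2P and 2N class structures are independent, so when both flags are
# present the mixture is their cross product.
model_classes <- function(model) {
  p <- as.list(model$params)
  mig_cls <- list(list(weight = 1, class = "base"))
  if ("2M2P" %in% model$flags)
    mig_cls <- list(list(weight = 1 - p$P1 - p$P2, class = "base"),
                    list(weight = p$P1, class = "noM12"),
                    list(weight = p$P2, class = "noM21"))
  sel_cls <- list(list(weight = 1, class = character()))
  if ("2N" %in% model$flags)
    sel_cls <- list(list(weight = 1 - p$nr, class = character()),
                    list(weight = p$nr, class = "bf"))
  cls <- list()
  for (m in mig_cls) for (s in sel_cls)
    cls[[length(cls) + 1]] <- list(weight = m$weight * s$weight,
                                   class = c(m$class, s$class))
  cls[vapply(cls, function(x) x$weight > 0, logical(1))]
}
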