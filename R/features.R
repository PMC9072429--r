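# Ion columns: 36 junction-corrected molar concentrations (10 extracellular,
# 26 intracellular), part of the 75-covariate block.
.EC_IONS <- c("ca", "mg", "na", "k", "cl", "cs", "hco3", "h2po4", "hpo4", "so4")
.IC_IONS <- c("ca", "mg", "na", "k", "cl", "cs", "br", "ba", "h2po4", "hpo4",
              "hco3", "gluconate", "qx314", "atp", "gtp", "egta", "oh", "so4",
              "phosphocreatine", "acetate", "methylsulfate", "nmdg", "tris",
              "ceso4", "pyruvate", "tea")

.SLOW_LEVELS <- c("intracellular_block", "extracellular_block", "pure_slow",
                  "contaminated", "absent")
.CPAMPA_LEVELS <- c("high", "low", "absent", "blocked")
.ORIENT_LEVELS <- c("coronal", "sagittal", "transverse", "horizontal",
                    "longitudinal", "magic_cut")
.REGION_LEVELS <- c("hippocampus", "entorhinal", "dorsal", "ventral",
                    "medial_lateral")

#' Physiological ionic concentrations (molar)
#'
#' A standard artificial-cerebrospinal-fluid bath and a
#' potassium-gluconate-free pipette solution used as the default ionic
#' covariates. Values are molar and serve as the reference ("standard")
#' condition of the normalization stage.
#'
#' @return Named numeric vector of 36 ion-column values.
#' @export
physiological_ions <- function() {
  ec <- stats::setNames(rep(0, length(.EC_IONS)), paste0("ec_", .EC_IONS))
  ec[c("ec_na", "ec_k", "ec_ca", "ec_mg", "ec_cl", "ec_hco3", "ec_h2po4")] <-
    c(0.151, 0.0025, 0.002, 0.001, 0.1335, 0.026, 0.00125)
  ic <- stats::setNames(rep(0, length(.IC_IONS)), paste0("ic_", .IC_IONS))
  ic[c("ic_k", "ic_na", "ic_cl", "ic_mg", "ic_atp", "ic_gtp", "ic_egta",
       "ic_phosphocreatine", "ic_hco3")] <-
    c(0.140, 0.010, 0.008, 0.001, 0.004, 0.0003, 0.0002, 0.010, 0.002)
  c(ec, ic)
}

#' Synthetic 122-entry neuron-type catalog
#'
#' The feature space one-hot encodes 122 presynaptic and 122 postsynaptic
#' neuron types. Curating the real hippocampal/entorhinal type catalog is
#' out of scope here, so the default catalog is a synthetic stand-in of
#' 122 generic type names; supply your own character vector to use a real
#' catalog.
#'
#' @param n Number of types; must be 122 for the standard feature layout.
#' @return Character vector of type names.
#' @export
neuron_type_catalog <- function(n = 122) {
  sprintf("NT%03d", seq_len(n))
}

#' Feature schema for the normalization model
#'
#' Fixes the deterministic, versioned column layout of the
#' 319-dimensional feature space: 122 presynaptic one-hot columns, 122
#' postsynaptic one-hot columns, and 75 covariate columns (stimulation
#' method 3; response type; contamination; slow-response status 5;
#' monoamine preservation; CP-AMPA density 4; reversal potentials 4; V_m;
#' temperature; ISI; species; sex; age; slice region 5; orientation 6;
#' thickness; recording subregion; 36 ionic concentrations; potency
#' flag).
#'
#' @param catalog Character vector of 122 neuron type names.
#' @return A list of class `feature_schema` with elements `catalog`,
#'   `columns` (319 column names) and `version`.
#' @export
feature_schema <- function(catalog = neuron_type_catalog()) {
  if (length(catalog) != 122 || anyDuplicated(catalog)) {
    stop("catalog must hold 122 unique type names", call. = FALSE)
  }
  cov_cols <- c(
    paste0("stim_", c("evoked", "unitary", "spontaneous")),
    "response_type", "contamination",
    paste0("slow_", .SLOW_LEVELS),
    "monoamine",
    paste0("cpampa_", .CPAMPA_LEVELS),
    "e_rev_ampa", "e_rev_nmda", "e_rev_gabaa", "e_rev_gabab",
    "v_m", "temperature", "isi", "species", "sex", "age",
    paste0("region_", .REGION_LEVELS),
    paste0("orient_", .ORIENT_LEVELS),
    "thickness", "subregion",
    names(physiological_ions()),
    "potency"
  )
  stopifnot(length(cov_cols) == 75)
  structure(list(
    catalog = catalog,
    columns = c(paste0("pre_", catalog), paste0("post_", catalog), cov_cols),
    version = "1"
  ), class = "feature_schema")
}

.onehot_rows <- function(values, levels, prefix) {
  m <- matrix(0, length(values), length(levels),
              dimnames = list(NULL, paste0(prefix, levels)))
  for (i in seq_along(values)) {
    v <- strsplit(values[i], "|", fixed = TRUE)[[1]]
    hit <- match(v, levels)
    if (anyNA(hit)) {
      stop("unknown level(s): ", paste(v[is.na(hit)], collapse = ", "),
           call. = FALSE)
    }
    m[i, hit] <- 1
  }
  m
}

#' Encode annotated recording metadata into the 319-feature space
#'
#' Deterministically maps raw record metadata to the versioned feature
#' layout of [feature_schema()]. Fuzzy pre/postsynaptic mappings
#' (`"TypeA|TypeB"`) become binary multi-hot columns. Species is encoded
#' 1 = rat, -1 = mouse, 0 = guinea pig; sex 1 = male, -1 = female,
#' 0 = unstated; stimulation uses three columns for four methods (all
#' zero = miniature). The ISI feature is set to 0 for records whose ST-P
#' targets are missing (the `NA` sentinel) and otherwise defaults to 50
#' ms - the mode of typical ISIs - when unreported.
#'
#' @param records Tibble of raw metadata (see [generate_ml_dataset()] for
#'   the expected columns; missing optional columns fall back to the
#'   standard condition). An optional logical column `stp_missing` marks
#'   records lacking the ST-P triple.
#' @param schema A [feature_schema()].
#' @return Numeric tibble with exactly 319 columns in schema order.
#' @export
encode_features <- function(records, schema = feature_schema()) {
  stopifnot(inherits(schema, "feature_schema"))
  records <- tibble::as_tibble(records)
  n <- nrow(records)
  col <- function(nm, default) {
    if (nm %in% names(records)) records[[nm]] else rep(default, n)
  }
  pre <- .onehot_rows(records$pre, schema$catalog, "pre_")
  post <- .onehot_rows(records$post, schema$catalog, "post_")
  if (any(rowSums(pre) == 0) || any(rowSums(post) == 0)) {
    stop("every record needs at least one pre- and post-synaptic type",
         call. = FALSE)
  }
  stim <- col("stimulation", "unitary")
  bad <- setdiff(unique(stim), c("evoked", "unitary", "spontaneous", "miniature"))
  if (length(bad)) stop("unknown stimulation method: ", bad[1], call. = FALSE)
  stim_m <- cbind(stim_evoked = as.numeric(stim == "evoked"),
                  stim_unitary = as.numeric(stim == "unitary"),
                  stim_spontaneous = as.numeric(stim == "spontaneous"))
  response <- col("response", "glutamatergic")
  species <- col("species", "rat")
  sex <- col("sex", "male")
  stp_missing <- as.logical(col("stp_missing", FALSE))
  isi <- as.numeric(col("isi", NA_real_))
  isi <- ifelse(stp_missing, 0, ifelse(is.na(isi), 50, isi))
  ions <- physiological_ions()
  ion_m <- vapply(names(ions), function(nm) as.numeric(col(nm, ions[[nm]])),
                  numeric(n))
  if (n == 1) ion_m <- matrix(ion_m, 1, dimnames = list(NULL, names(ions)))
  m <- cbind(
    pre, post, stim_m,
    response_type = ifelse(response == "GABAergic", 1, -1),
    contamination = as.numeric(col("contamination", FALSE)),
    .onehot_rows(as.character(col("slow_status", "absent")), .SLOW_LEVELS, "slow_"),
    monoamine = as.numeric(col("monoamine", TRUE)),
    .onehot_rows(as.character(col("cpampa", "absent")), .CPAMPA_LEVELS, "cpampa_"),
    e_rev_ampa = as.numeric(col("e_rev_ampa", 0)),
    e_rev_nmda = as.numeric(col("e_rev_nmda", 0)),
    e_rev_gabaa = as.numeric(col("e_rev_gabaa", -70)),
    e_rev_gabab = as.numeric(col("e_rev_gabab", -90)),
    v_m = as.numeric(col("v_m", -70)),
    temperature = as.numeric(col("temperature", 32)),
    isi = isi,
    species = {
      sp <- c(rat = 1, mouse = -1, guinea_pig = 0)[species]
      if (anyNA(sp)) stop("unknown species", call. = FALSE)
      unname(sp)
    },
    sex = {
      sx <- c(male = 1, female = -1)[sex]
      sx[is.na(sx)] <- 0  # both or unstated
      unname(sx)
    },
    age = as.numeric(col("age", 56)),
    .onehot_rows(as.character(col("slice_region", "hippocampus|dorsal")),
                 .REGION_LEVELS, "region_"),
    .onehot_rows(as.character(col("orientation", "transverse")),
                 .ORIENT_LEVELS, "orient_"),
    thickness = as.numeric(col("thickness", 300)),
    subregion = c(soma = 0, dendrite = 1, ais = -1)[as.character(col("subregion", "soma"))],
    ion_m,
    potency = as.numeric(col("potency", FALSE))
  )
  if (anyNA(m[, "age"])) {
    stop("age must be provided for every record (estimation from weight or ",
         "strain is not supported)", call. = FALSE)
  }
  colnames(m) <- schema$columns
  out <- tibble::as_tibble(as.data.frame(m))
  stopifnot(ncol(out) == 319)
  out
}

#' The standard recording condition used for normalization
#'
#' Unitary fast responses of adult (P56) male rats recorded in voltage
#' clamp at body temperature with physiological bath and pipette
#' solutions. Recording modality is represented through the membrane
#' potential feature: the voltage-clamp holding potential (-70 mV) versus
#' a current-clamp resting potential (-65 mV).
#'
#' @return One-row tibble of raw record metadata (without pre/post types).
#' @export
standard_condition <- function() {
  tibble::tibble(
    stimulation = "unitary", response = "glutamatergic",
    contamination = FALSE, slow_status = "absent", monoamine = TRUE,
    cpampa = "absent", e_rev_ampa = 0, e_rev_nmda = 0, e_rev_gabaa = -70,
    e_rev_gabab = -90, v_m = -70, temperature = 32, isi = 50,
    species = "rat", sex = "male", age = 56,
    slice_region = "hippocampus|dorsal", orientation = "transverse",
    thickness = 300, subregion = "soma", potency = FALSE,
    stp_missing = FALSE
  )
}

#' Grid of the 32 condition permutations
#'
#' All combinations of species (rat/mouse), sex (male/female), age
#' (P56/P14), temperature (body 32 / room 22) and recording modality
#' (voltage clamp / current clamp), applied on top of a base condition.
#'
#' @param base One-row condition tibble; default [standard_condition()].
#' @return Tibble of 32 condition rows with an added `modality` column.
#' @export
condition_grid <- function(base = standard_condition()) {
  grid <- expand.grid(species = c("rat", "mouse"), sex = c("male", "female"),
                      age = c(56, 14), temperature = c(32, 22),
                      modality = c("voltage_clamp", "current_clamp"),
                      stringsAsFactors = FALSE)
  out <- base[rep(1, nrow(grid)), ]
  out$species <- grid$species
  out$sex <- grid$sex
  out$age <- grid$age
  out$temperature <- grid$temperature
  out$v_m <- ifelse(grid$modality == "voltage_clamp", -70, -65)
  out$modality <- grid$modality
  out
}

#' Augment records with amplitude/potency pseudo-signals
#'
#' Amplitude and potency differ by the treatment of failed events: when
#' failures are excluded from the average, the peak quantifies potency.
#' When the failure rate `f` of the first event is known the two are
#' interconvertible, `potency = amplitude / (1 - f)`, and each real
#' record can donate one pseudo-record of the other kind with a
#' correspondingly converted conductance target and flipped potency
#' flag.
#'
#' @param records Raw metadata tibble with a logical `potency` column and
#'   a numeric `failure_rate` column (`NA` when unknown).
#' @param targets Matching target tibble (column `g`).
#' @return A list with augmented `records` and `targets`; rows without a
#'   known failure rate are passed through unchanged.
#' @export
augment_potency <- function(records, targets) {
  records <- tibble::as_tibble(records)
  targets <- tibble::as_tibble(targets)
  stopifnot(nrow(records) == nrow(targets))
  if (!"failure_rate" %in% names(records)) {
    return(list(records = records, targets = targets))
  }
  f <- records$failure_rate
  ok <- !is.na(f) & f >= 0 & f < 1
  if (!any(ok)) return(list(records = records, targets = targets))
  pseudo_r <- records[ok, ]
  pseudo_t <- targets[ok, ]
  is_pot <- as.logical(pseudo_r$potency)
  # amplitude -> potency scales g up by 1/(1 - f); potency -> amplitude down
  scale <- ifelse(is_pot, 1 - f[ok], 1 / (1 - f[ok]))
  pseudo_t$g <- pseudo_t$g * scale
  pseudo_r$potency <- !is_pot
  list(records = dplyr::bind_rows(records, pseudo_r),
       targets = dplyr::bind_rows(targets, pseudo_t))
}
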