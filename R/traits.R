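#' Canonical salt-tolerance trait names
#'
#' The 14 seedling salt-tolerance traits used throughout the package, in
#' canonical column order: the three growth-trait stress indices (RGR, RNIL,
#' RLER), the leaf senescence score (Sen), shoot and root water contents
#' (SWC, RWC), shoot and root Na+ concentrations (SNC, RNC) and their ratio
#' (SN/RN), shoot and root K+ concentrations (SKC, RKC) and their ratio
#' (SK/RK), and the shoot and root K+/Na+ ratios (SK/N, RK/N).
#'
#' @return Character vector of length 14.
#' @export
trait_names <- function() {
  c("RGR", "RNIL", "RLER", "Sen", "SWC", "RWC", "SNC", "RNC",
    "SN/RN", "SKC", "RKC", "SK/RK", "SK/N", "RK/N")
}

#' Default trait direction map
#'
#' Direction of each trait's association with salt tolerance. Traits that
#' increase in sensitive material under stress (senescence, Na+
#' concentrations and their shoot/root ratio, and the K+ concentrations,
#' which rise together with Na+) are `"negative"`; the remaining eight are
#' `"positive"`. Membership scoring flips negative-direction traits so that
#' higher membership always means more tolerant.
#'
#' @return Named character vector over [trait_names()], values `"positive"`
#'   or `"negative"`.
#' @export
default_trait_directions <- function() {
  dirs <- stats::setNames(rep("positive", 14L), trait_names())
  dirs[c("Sen", "SNC", "RNC", "SN/RN", "SKC", "RKC")] <- "negative"
  dirs
}

#' Read a trait direction map from YAML
#'
#' @param path YAML file mapping trait name to `positive`/`negative`.
#'   Unlisted traits take the default direction.
#' @return Named character vector as [default_trait_directions()].
#' @export
load_trait_directions <- function(path) {
  dirs <- default_trait_directions()
  user <- yaml::read_yaml(path)
  bad <- setdiff(names(user), trait_names())
  if (length(bad) > 0L)
    stop("unknown trait(s) in direction map: ", paste(bad, collapse = ", "))
  vals <- unlist(user)
  if (!all(vals %in% c("positive", "negative")))
    stop("directions must be 'positive' or 'negative'")
  dirs[names(vals)] <- vals
  dirs
}

#' Construct a trait table
#'
#' A trait table is a data frame with a `genotype_id` column and the 14
#' canonical trait columns, carrying the trait direction map as an
#' attribute. Extra columns are preserved but ignored by all computations.
#'
#' @param df Data frame with `genotype_id` plus the 14 trait columns.
#' @param directions Named direction vector; see
#'   [default_trait_directions()].
#' @return Object of class `trait_table`.
#' @export
trait_table <- function(df, directions = default_trait_directions()) {
  stopifnot(is.data.frame(df))
  if (!"genotype_id" %in% names(df)) stop("missing 'genotype_id' column")
  missing_tr <- setdiff(trait_names(), names(df))
  if (length(missing_tr) > 0L)
    stop("missing trait column(s): ", paste(missing_tr, collapse = ", "))
  missing_dir <- setdiff(trait_names(), names(directions))
  if (length(missing_dir) > 0L)
    stop("direction undefined for: ", paste(missing_dir, collapse = ", "))
  if (anyDuplicated(df$genotype_id))
    stop("duplicated genotype_id values")
  df$genotype_id <- as.character(df$genotype_id)
  structure(as.data.frame(df), directions = directions[trait_names()],
            class = c("trait_table", "data.frame"))
}

#' Extract the genotype-by-trait value matrix
#'
#' @param table A `trait_table`.
#' @return Numeric matrix, rows named by genotype, columns in canonical
#'   trait order.
#' @export
trait_values <- function(table) {
  m <- as.matrix(as.data.frame(table)[, trait_names(), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- table$genotype_id
  m
}

#' Trait directions of a trait table
#' @param table A `trait_table`.
#' @return Named character vector of directions.
#' @export
trait_directions <- function(table) attr(table, "directions")

#' @export
print.trait_table <- function(x, ...) {
  cat(sprintf("<trait_table> %d genotypes x %d traits\n",
              nrow(x), length(trait_names())))
  NextMethod()
}

#' Growth rates from a time-series phenotype record
#'
#' Computes the shoot growth rate GR (cm/day) as the mean of the daily
#' height increase over 2--7 DAS and 2--17 DAS, the number of leaves
#' increased NIL as the 17 DAS count minus the 1 DAS count, and the leaf
#' expansion rate LER (cm/day) as the mean daily elongation of the marked
#' leaf over 2--7 DAS and 2--12 DAS. DAS = days after starting the stress
#' treatment.
#'
#' @param heights Named numeric vector of plant heights (cm) with names
#'   `"2"`, `"7"`, `"17"` (DAS).
#' @param leaf_counts Named numeric vector of leaf counts with names `"1"`,
#'   `"17"`.
#' @param leaf_lengths Named numeric vector of marked-leaf lengths (cm) with
#'   names `"2"`, `"7"`, `"12"`.
#' @return List with components `GR`, `NIL`, `LER`; a component is only
#'   computed when its series is supplied.
#' @export
derive_growth_rates <- function(heights = NULL, leaf_counts = NULL,
                                leaf_lengths = NULL) {
  need <- function(x, das, trait) {
    das <- as.character(das)
    miss <- das[!das %in% names(x)]
    if (length(miss) > 0L)
      stop(sprintf("missing timepoint(s) DAS %s: cannot compute %s",
                   paste(miss, collapse = ","), trait))
    as.numeric(x[das])
  }
  out <- list()
  if (!is.null(heights)) {
    h <- need(heights, c(2, 7, 17), "GR")
    out$GR <- mean(c((h[2] - h[1]) / 5, (h[3] - h[1]) / 15))
  }
  if (!is.null(leaf_counts)) {
    l <- need(leaf_counts, c(1, 17), "NIL")
    out$NIL <- l[2] - l[1]
  }
  if (!is.null(leaf_lengths)) {
    L <- need(leaf_lengths, c(2, 7, 12), "LER")
    out$LER <- mean(c((L[2] - L[1]) / 5, (L[3] - L[1]) / 10))
  }
  out
}

#' Salt tolerance and salt-injury indices
#'
#' STI is the ratio of a growth trait's value under stress to its value
#' under control for the same genotype; SII = 1 - STI quantifies the
#' fractional injury.
#'
#' @param stress,control Non-negative trait values; `control` must be
#'   strictly positive. Vectorized.
#' @return List with numeric components `STI` and `SII`.
#' @export
compute_sti_sii <- function(stress, control) {
  if (any(control <= 0))
    stop("control value must be > 0 to form the stress/control ratio")
  sti <- stress / control
  list(STI = sti, SII = 1 - sti)
}

#' Tissue water content
#'
#' Default fresh-mass basis: WC% = (fresh - dry) / fresh x 100. A dry-mass
#' basis ((fresh - dry) / dry x 100) is selectable; the fresh basis is the
#' package default and is documented as an assumption in the methods
#' vignette.
#'
#' @param fresh,dry Fresh and dry masses (g); `0 <= dry <= fresh`,
#'   `fresh > 0`. Vectorized.
#' @param basis `"fresh"` (default) or `"dry"`.
#' @return Water content in percent.
#' @export
compute_water_content <- function(fresh, dry, basis = c("fresh", "dry")) {
  basis <- match.arg(basis)
  if (any(fresh <= 0)) stop("fresh mass must be > 0")
  if (any(dry < 0) || any(dry > fresh))
    stop("invalid masses: need 0 <= dry <= fresh")
  if (basis == "fresh") (fresh - dry) / fresh * 100 else {
    if (any(dry == 0)) stop("dry mass must be > 0 for the dry basis")
    (fresh - dry) / dry * 100
  }
}

# Derived per-replicate quantities from one genotype x treatment x replicate
# block of long-format rows. Returns a named list of scalars (NA when the
# underlying measures are absent).
.replicate_derived <- function(rows, water_basis) {
  val <- function(measure, das = NA) {
    sel <- rows$measure == measure &
      (is.na(das) | (!is.na(rows$das) & rows$das == das))
    v <- rows$value[sel]
    if (length(v) == 0L) NA_real_ else v[[1L]]
  }
  series <- function(measure, das) {
    v <- vapply(das, function(d) val(measure, d), numeric(1))
    stats::setNames(v, as.character(das))
  }
  out <- list(GR = NA_real_, NIL = NA_real_, LER = NA_real_)
  h <- series("height_cm", c(2, 7, 17))
  if (!anyNA(h)) out$GR <- derive_growth_rates(heights = h)$GR
  lc <- series("leaf_count", c(1, 17))
  if (!anyNA(lc)) out$NIL <- derive_growth_rates(leaf_counts = lc)$NIL
  ll <- series("leaf_length_cm", c(2, 7, 12))
  if (!anyNA(ll)) out$LER <- derive_growth_rates(leaf_lengths = ll)$LER
  sf <- val("shoot_fresh_g"); sd_ <- val("shoot_dry_g")
  rf <- val("root_fresh_g");  rd <- val("root_dry_g")
  out$SWC <- if (!is.na(sf) && !is.na(sd_))
    compute_water_content(sf, sd_, basis = water_basis) else NA_real_
  out$RWC <- if (!is.na(rf) && !is.na(rd))
    compute_water_content(rf, rd, basis = water_basis) else NA_real_
  out$Sen <- val("senescence_score")
  out$SNC <- val("shoot_na_mg_g"); out$RNC <- val("root_na_mg_g")
  out$SKC <- val("shoot_k_mg_g");  out$RKC <- val("root_k_mg_g")
  out
}

#' Assemble the 14-trait table from raw phenotype records
#'
#' Takes long-format raw phenotype records (columns `genotype_id`,
#' `treatment`, `replicate`, `measure`, `das`, `value`), derives the
#' per-replicate growth traits, averages replicates within genotype x
#' treatment, and builds the genotype x 14-trait table: RGR/RNIL/RLER as the
#' stress/control ratio (STI) of GR/NIL/LER, the stress-only traits (Sen,
#' SWC, RWC, SNC, RNC, SKC, RKC) from the stress arm, and the four ion
#' ratios (SN/RN, SK/RK, SK/N, RK/N) from the averaged base concentrations,
#' so the ratio identities hold row-wise by construction.
#'
#' Genotypes missing a treatment arm are excluded with a warning and listed
#' in the `exclusions` attribute of the result; a control-arm growth trait
#' averaging to zero yields `NA` for that stress index rather than an
#' infinite ratio.
#'
#' @param records Data frame of long-format raw records. Recognized
#'   `measure` values: `height_cm`, `leaf_count`, `leaf_length_cm` (with
#'   `das`), `shoot_fresh_g`, `shoot_dry_g`, `root_fresh_g`, `root_dry_g`,
#'   `senescence_score`, `shoot_na_mg_g`, `root_na_mg_g`, `shoot_k_mg_g`,
#'   `root_k_mg_g`.
#' @param directions Trait direction map for the resulting table.
#' @param water_basis Basis for water content, see
#'   [compute_water_content()].
#' @return A [trait_table()] with attribute `exclusions` (data frame of
#'   excluded genotypes and reasons). Row order follows first appearance of
#'   each genotype in `records`.
#' @export
assemble_trait_table <- function(records,
                                 directions = default_trait_directions(),
                                 water_basis = "fresh") {
  req <- c("genotype_id", "treatment", "replicate", "measure", "value")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L)
    stop("records missing column(s): ", paste(miss, collapse = ", "))
  if (!"das" %in% names(records)) records$das <- NA_real_
  if (!all(records$treatment %in% c("control", "stress")))
    stop("treatment must be 'control' or 'stress'")
  if (any(records$value < 0, na.rm = TRUE))
    stop("raw phenotype values must be >= 0")

  geno_order <- unique(as.character(records$genotype_id))
  rows <- vector("list", length(geno_order))
  excl <- list()

  arm_means <- function(g, trt) {
    arm <- records[records$genotype_id == g & records$treatment == trt, ,
                   drop = FALSE]
    if (nrow(arm) == 0L) return(NULL)
    reps <- lapply(split(arm, arm$replicate), .replicate_derived,
                   water_basis = water_basis)
    nm <- names(reps[[1L]])
    stats::setNames(vapply(nm, function(f) {
      v <- vapply(reps, `[[`, numeric(1), f)
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1)), nm)
  }

  for (g in geno_order) {
    ck <- arm_means(g, "control")
    st <- arm_means(g, "stress")
    if (is.null(ck) || is.null(st)) {
      excl[[g]] <- sprintf("missing %s arm",
                           if (is.null(ck)) "control" else "stress")
      next
    }
    sti <- function(trait) {
      if (is.na(st[[trait]]) || is.na(ck[[trait]]) || ck[[trait]] <= 0)
        NA_real_ else st[[trait]] / ck[[trait]]
    }
    ratio <- function(num, den)
      if (is.na(st[[num]]) || is.na(st[[den]]) || st[[den]] == 0)
        NA_real_ else st[[num]] / st[[den]]
    rows[[g]] <- data.frame(
      genotype_id = g,
      RGR = sti("GR"), RNIL = sti("NIL"), RLER = sti("LER"),
      Sen = st[["Sen"]], SWC = st[["SWC"]], RWC = st[["RWC"]],
      SNC = st[["SNC"]], RNC = st[["RNC"]],
      `SN/RN` = ratio("SNC", "RNC"),
      SKC = st[["SKC"]], RKC = st[["RKC"]],
      `SK/RK` = ratio("SKC", "RKC"),
      `SK/N` = ratio("SKC", "SNC"), `RK/N` = ratio("RKC", "RNC"),
      check.names = FALSE)
  }

  kept <- rows[!vapply(rows, is.null, logical(1))]
  if (length(kept) == 0L) stop("no genotype has both treatment arms")
  out <- trait_table(do.call(rbind, c(kept, list(make.row.names = FALSE))),
                     directions = directions)
  exclusions <- data.frame(genotype_id = names(excl),
                           reason = unlist(excl, use.names = FALSE),
                           stringsAsFactors = FALSE)
  if (nrow(exclusions) > 0L)
    warning(sprintf("excluded %d genotype(s) lacking a treatment arm: %s",
                    nrow(exclusions),
                    paste(exclusions$genotype_id, collapse = ", ")))
  attr(out, "exclusions") <- exclusions
  out
}

#' Read / write a trait table as CSV
#'
#' Wide CSV with a `genotype_id` column and the 14 canonical trait columns.
#' Lines starting with `#` are treated as provenance comments. Values
#' round-trip to at least 12 significant digits. Unknown columns are
#' preserved in the data frame but ignored by computations.
#'
#' @param path CSV file path.
#' @param directions Direction map attached on load.
#' @return `load_trait_table`: a [trait_table()].
#' @export
load_trait_table <- function(path, directions = default_trait_directions()) {
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#",
                        stringsAsFactors = FALSE)
  missing_tr <- setdiff(c("genotype_id", trait_names()), names(df))
  if (length(missing_tr) > 0L)
    stop("trait table at '", path, "' missing column(s): ",
         paste(missing_tr, collapse = ", "))
  trait_table(df, directions = directions)
}

#' @rdname load_trait_table
#' @param table A `trait_table` to write.
#' @param provenance Optional character scalar written as a leading `#`
#'   comment line.
#' @export
write_trait_table <- function(table, path, provenance = NULL) {
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 15,
                                                 format = "g"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
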