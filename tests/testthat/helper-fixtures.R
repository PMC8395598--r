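# Shared fixtures, built once per test session. Helpers are re-sourced per
# test file, so the cache lives in the global environment.

if (!exists(".lungreg_cache", envir = globalenv()))
  assign(".lungreg_cache", new.env(parent = emptyenv()), envir = globalenv())

cached <- function(name, builder) {
  cache <- get(".lungreg_cache", envir = globalenv())
  if (!exists(name, envir = cache)) assign(name, builder(), envir = cache)
  get(name, envir = cache)
}

# small, fast phantom for module-level tests
small_case <- function() cached("small_case", function() {
  phantom_case(64, 2, seed = 2, max_displacement_mm = 10, rild_fraction = 0)
})

small_stacks <- function() cached("small_stacks", function() {
  case <- small_case()
  list(ref = feature_stack(case$baseline, case$lung_mask_b,
                           case$airway_mask_b),
       flt = feature_stack(case$followup, case$lung_mask_f,
                           case$airway_mask_f))
})

# the study-condition phantom: 96^3 at 2 mm, 15 mm truth displacement
acc_clean_case <- function() cached("acc_clean_case", function() {
  phantom_case(96, 2, seed = 1, max_displacement_mm = 15, rild_fraction = 0)
})

acc_rild_case <- function() cached("acc_rild_case", function() {
  clean <- acc_clean_case()
  synthesize_followup(clean, clean$truth_velocity, rild_fraction = 0.25)
})

acc_stacks <- function(which = c("clean", "rild")) {
  which <- match.arg(which)
  cached(paste0("acc_stacks_", which), function() {
    case <- if (which == "clean") acc_clean_case() else acc_rild_case()
    list(ref = feature_stack(case$baseline, case$lung_mask_b,
                             case$airway_mask_b),
         flt = feature_stack(case$followup, case$lung_mask_f,
                             case$airway_mask_f))
  })
}

acc_fit <- function(which = c("mc_clean", "mc_rild", "int_rild")) {
  which <- match.arg(which)
  cached(paste0("acc_fit_", which), function() {
    config <- reg_config()
    if (which == "int_rild") {
      case <- acc_rild_case()
      register_intensity(case$baseline, case$followup, config,
                         case$lung_mask_b, case$lung_mask_f)
    } else {
      kind <- if (which == "mc_clean") "clean" else "rild"
      st <- acc_stacks(kind)
      case <- if (kind == "clean") acc_clean_case() else acc_rild_case()
      register_multichannel(st$ref, st$flt, config, case$lung_mask_b,
                            case$lung_mask_f)
    }
  })
}

acc_eval <- function(which = c("mc_clean", "mc_rild", "int_rild")) {
  which <- match.arg(which)
  cached(paste0("acc_eval_", which), function() {
    case <- if (which == "mc_clean") acc_clean_case() else acc_rild_case()
    evaluate_registration(acc_fit(which), case$landmarks_b, case$landmarks_f)
  })
}

# tiny deterministic grids for oracle tests
rand_image <- function(dims, seed = 1, spacing = 2) {
  set.seed(seed)
  vol_image(array(stats::runif(prod(dims)), dims),
            diag(c(rep(spacing, 3), 1)))
}

rand_velocity <- function(ref, spacing_mm, seed = 1, sd = 1) {
  set.seed(seed)
  v <- velocity_field_zero(ref, spacing_mm)
  v$coef <- array(stats::rnorm(length(v$coef), sd = sd), dim(v$coef))
  v
}
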