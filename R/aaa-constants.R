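# Package-level constants shared across modules.

# Severity class labels, in increasing order of depression severity.
SEVERITY_LEVELS <- c("none_mild", "moderate", "severe")

# Age-group labels; the 30/31 and 45/46 boundaries put age 30 in the first
# group and 46 in the last.
AGE_GROUP_LEVELS <- c("<=30", "31-45", ">=46")

# PHQ-9 item short names, in questionnaire order. Item 1 is diminished
# interest (anhedonia) and item 2 is depressed mood; the reliability trap
# question paraphrases item 2.
PHQ9_ITEMS <- c(
  "diminished_interest", "depressed_mood", "sleep_problems", "fatigue",
  "appetite_problems", "worthlessness", "concentration_problems",
  "psychomotor_change", "suicidal_ideation"
)

# Severity model families exposed by run_loso_severity().
SEVERITY_MODELS <- c("xgb", "rf", "svm", "multinom")

# Boosting rounds for the gradient-boosted models (library defaults
# otherwise, with a fixed seed).
XGB_NROUNDS <- 60L

# Latent per-item AR(1) means by severity group: totals around 4.5 / 14 /
# 21.5 sit inside the none-mild / moderate / severe score bands.
GROUP_ITEM_MEANS <- c(none_mild = 0.50, moderate = 1.55, severe = 2.40)

APP_CATEGORIES <- c("social", "finance", "media", "tools", "work", "study",
                    "lifestyle")
ACTIVITY_ACTIVE <- c("walking", "running", "cycling")
ACTIVITY_INACTIVE <- c("still", "in_vehicle")

# daily base event rates of the simulated event sources
EVENT_BASE_RATE <- c(app_usage = 25, call_log = 6, keystroke = 12,
                     microphone = 40, notifications = 30, pedometer = 15,
                     physical_activity = 10, screen = 35)
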