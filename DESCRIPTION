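Package: placenav
Title: Simulation and Trajectory Analytics for a VR Place-Preference
    Navigation Task
Version: 1.0.0
Author: placenav developers
Maintainer: placenav developers <placenav@example.org>
Description: Tools for simulating and analysing rodent goal-directed
    navigation in a circular virtual-reality arena with two hidden reward
    zones of unequal value. Provides a synthetic-agent trajectory generator
    (novice, expert, and hippocampal-inactivation regimes), per-trial
    trajectory metrics (departing direction, perimeter-crossing direction,
    deviation angles, crossing counts, travel distance), circular statistics
    (mean resultant vectors, Kuiper two-sample permutation test,
    Watson-Williams test with a concentration applicability gate), the
    within-subject comparison workflow (Wilcoxon signed-rank,
    repeated-measures ANOVA with Greenhouse-Geisser correction and
    Bonferroni post hoc tests), and a CSV/JSON pipeline with a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
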