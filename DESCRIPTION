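Package: irtmiss
Title: Treatments of Missing Item Responses in Item Response Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how missing item responses affect population
    estimates in large-scale educational assessments. Implements the
    Mislevy-Wu shared-parameter model for nonignorable item omissions
    together with the standard alternatives: scoring omissions as wrong or
    partially correct, ignoring them in the likelihood, latent-ignorable
    joint models over a bivariate (ability, response propensity) quadrature,
    model-based multiple imputation, and fully conditional specification
    imputation with partial least squares dimension reduction and predictive
    mean matching. Includes marginal maximum likelihood EM estimation of the
    two-parameter logistic model with fractional responses, person weights
    and a latent background model, Haberman linking of group-specific item
    parameters, transformation to a reporting metric, model-fit statistics
    (AIC, BIC, Gilula-Haberman penalty), balanced-repeated-replication
    standard errors, and a simulation engine that evaluates bias and RMSE
    of linked means and standard deviations with jackknife Monte Carlo
    standard errors.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    pracma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
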