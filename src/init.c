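#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>

extern SEXP c_ssa_cell(SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP, SEXP);
void lac_initmod(void (*odeparms)(int *, double *));
void lac_derivs(int *, double *, double *, double *, double *, int *);

static const R_CallMethodDef CallEntries[] = {
  {"c_ssa_cell", (DL_FUNC) &c_ssa_cell, 8},
  {NULL, NULL, 0}
};

/* the ODE right-hand side is registered so that deSolve can look the
 * symbols up by name (dllname = "lacpop") */
static const R_CMethodDef CEntries[] = {
  {"lac_initmod", (DL_FUNC) &lac_initmod, 1},
  {"lac_derivs",  (DL_FUNC) &lac_derivs,  6},
  {NULL, NULL, 0}
};

void R_init_lacpop(DllInfo *dll) {
  R_registerRoutines(dll, CEntries, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
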