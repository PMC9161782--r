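# Default hierarchical gating configuration for the 10-marker immune panel.
# Per-marker positivity thresholds are on the unit intensity scale; rules are
# evaluated in order and the first full match labels the cell, so more
# specific rules must precede their parents. `populations` defines aggregate
# (parent) populations as unions of leaf phenotypes, with the denominator
# used for proportion summaries.
thresholds:
  CD45: 0.07
  CD3: 0.10
  CD8: 0.10
  FOXP3: 0.10
  CD20: 0.10
  CD68: 0.10
  CSF1R: 0.10
  CD163: 0.10
  CD1C: 0.10
  KI67: 0.10
rules:
  - label: Proliferating CD8 T cells
    require: {CD45: "+", CD3: "+", CD8: "+", KI67: "+"}
  - label: Proliferating Treg cells
    require: {CD45: "+", CD3: "+", CD8: "-", FOXP3: "+", KI67: "+"}
  - label: CD8 T cells
    require: {CD45: "+", CD3: "+", CD8: "+"}
  - label: T regulatory cells
    require: {CD45: "+", CD3: "+", CD8: "-", FOXP3: "+"}
  - label: Other Th cells
    require: {CD45: "+", CD3: "+", CD8: "-", FOXP3: "-"}
  - label: B cells
    require: {CD45: "+", CD3: "-", CD20: "+"}
  - label: CD1C+ myeloid dendritic cells
    require: {CD45: "+", CD3: "-", CD20: "-", CD1C: "+"}
  - label: CD163+ myelomonocytic cells
    require: {CD45: "+", CD3: "-", CD20: "-", CD1C: "-", CD68: "+",
              CSF1R: "+", CD163: "+"}
  - label: CD163- myelomonocytic cells
    require: {CD45: "+", CD3: "-", CD20: "-", CD1C: "-", CD68: "+",
              CSF1R: "+", CD163: "-"}
  - label: Monocytes macrophages fibrocytes
    require: {CD45: "+", CD3: "-", CD20: "-", CD1C: "-", CD68: "+",
              CSF1R: "-"}
  - label: Other myeloid lineages
    require: {CD45: "+", CD3: "-", CD20: "-"}
  - label: Other CD45+ immune cells
    require: {CD45: "+"}
  - label: Non-immune cells
    require: {}
populations:
  - name: Pan immune cells
    members: [Proliferating CD8 T cells, Proliferating Treg cells,
              CD8 T cells, T regulatory cells, Other Th cells, B cells,
              CD1C+ myeloid dendritic cells, CD163+ myelomonocytic cells,
              CD163- myelomonocytic cells, Monocytes macrophages fibrocytes,
              Other myeloid lineages, Other CD45+ immune cells]
    denominator: Total cells
  - name: T cells
    members: [Proliferating CD8 T cells, Proliferating Treg cells,
              CD8 T cells, T regulatory cells, Other Th cells]
    denominator: Pan immune cells
  - name: Total CD8 T cells
    members: [CD8 T cells, Proliferating CD8 T cells]
    denominator: T cells
  - name: CD8- T cells
    members: [T regulatory cells, Proliferating Treg cells, Other Th cells]
    denominator: T cells
  - name: Total Treg cells
    members: [T regulatory cells, Proliferating Treg cells]
    denominator: T cells
  - name: Presumptive myeloid lineages
    members: [CD1C+ myeloid dendritic cells, CD163+ myelomonocytic cells,
              CD163- myelomonocytic cells, Monocytes macrophages fibrocytes,
              Other myeloid lineages]
    denominator: Pan immune cells
  - name: Total myelomonocytic cells
    members: [CD163+ myelomonocytic cells, CD163- myelomonocytic cells]
    denominator: Presumptive myeloid lineages
  - name: CD163+ myelomonocytic cells
    members: [CD163+ myelomonocytic cells]
    denominator: Total myelomonocytic cells
  - name: B cells
    members: [B cells]
    denominator: Pan immune cells
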