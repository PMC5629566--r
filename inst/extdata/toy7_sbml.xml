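<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toy7" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A" name="A" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" name="B" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="C" name="C" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
      <species id="D" name="D" compartment="c" boundaryCondition="false" hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="fb_zero" value="0" constant="true"/>
      <parameter id="fb_hundred" value="100" constant="true"/>
      <parameter id="fb_ten" value="10" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="UP" reversible="false" fast="false" fbc:lowerFluxBound="fb_ten" fbc:upperFluxBound="fb_ten">
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R4" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="0.5" constant="true"/>
          <speciesReference species="C" stoichiometry="0.5" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R5" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="WD" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="D" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="BIOM" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="CHEM" reversible="false" fast="false" fbc:lowerFluxBound="fb_zero" fbc:upperFluxBound="fb_hundred">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="BIOM" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
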