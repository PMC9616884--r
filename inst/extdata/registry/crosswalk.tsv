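meaning_id	meaning_text	omop	openehr	fhir	cdisc	cardinality
metadata_id	Unique and persistent identifier of the metadata	metadata_concept_id	versionID	Meta.versionID	ODM/Study/MetaDataVersion
metadata_version	Version of the metadata	metadata_concept_id	versionID	Meta.versionID	ODM/Study/MetaDataVersion
metadata_type	Identifier of the type of information	metadata_type_concept_id
metadata_version_name	Name of the metadata version	name	name		ODM/Study/MetaDataVersion/Name
metadata_value_string	Metadata value as string	value_as_string
metadata_value_concept	Metadata value as concept	value_as_concept_id
metadata_date	Date of the metadata creation	metadata_date		DataRequirement	ODM/AsOfDatetime
metadata_datetime	Datetime of the metadata creation	metadata_datetime		Meta.lastUpdated	ODM/AsOfDatetime
source_name	Full name of the source	cdm_source_name	resource_description:parent_resource	Meta.profile	def:Origin
source_abbreviation	Abbreviation of the source name, if applicable	cdm_source_abbreviation			def:Origin
source_contributor	contributor or publisher of the source data	cdm_holder	resource_description:original_author|resource_description:original_publisher	Contributor	def:Origin	openehr=merge
affiliate_dataset_id	Globally unique identifier of the data, which the metadata is associated with	source_description_reference	resource_description_item:original_resource	DataRequirement.Profile	def:Origin
reference_data	References to other data via name or description		resource_description:references	RelatedArtifact	def:LeafElement
data_lifecycle_state	State of the data during its lifecycle (creation, processing, analysis, preservation, access, reuse)		resource_description:lifecycle_state		def:AnnotatedCRF
usage_license_copyright	clear and accessible data usage license		resource_description:copyright
usage_context	Context in which the data should be used		resource_description_item:use	UsageContext	StudyDescription
source_information	Additional information about the source of the data	source_description	resource_description_item:purpose	DataRequirement.type	def:Origin
data_item_language	Language of the data items		resource_description_item:language
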